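{"n_groups":5,"survey_area_km2":1.09830915570003,"group_density":4.55245226177975,"true_n_groups":4,"true_density":4,"seed":2024}
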