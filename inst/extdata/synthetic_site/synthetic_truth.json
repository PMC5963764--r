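{"n_groups":4,"true_density":4,"centers":[{"x":702.165524289012,"y":392.520519578829},{"x":741.129710478708,"y":771.864759689197},{"x":266.186648281291,"y":717.929123714566},{"x":228.361735958606,"y":267.195505043492}],"activity_sites":[{"x":794.373353777196,"y":265.604786964718,"record_type":"fox_cub","group":1,"site":1},{"x":755.111201564545,"y":219.8355882441,"record_type":"fox_cub","group":1,"site":2},{"x":700.956344203292,"y":396.961671790257,"record_type":"fox_cub","group":1,"site":3},{"x":662.85544771097,"y":802.215968351158,"record_type":"fox_cub","group":2,"site":1},{"x":691.710389113817,"y":962.895931461683,"record_type":"fox_cub","group":2,"site":2},{"x":187.644123656437,"y":548.385173567065,"record_type":"fox_cub","group":3,"site":1},{"x":446.092962866832,"y":781.584509784291,"record_type":"fox_cub","group":3,"site":2},{"x":420.593721517823,"y":684.554044158201,"record_type":"fox_cub","group":3,"site":3},{"x":390.187934977591,"y":735.289337409064,"record_type":"fox_cub","group":3,"site":4},{"x":155.257197499322,"y":570.440876907667,"record_type":"fox_cub","group":3,"site":5},{"x":79.7972389461601,"y":354.213854213398,"record_type":"fox_cub","group":4,"site":1},{"x":203.777309934683,"y":399.535198879218,"record_type":"fox_cub","group":4,"site":2},{"x":149.241391922578,"y":151.785025453975,"record_type":"fox_cub","group":4,"site":3},{"x":126.761858281905,"y":126.458966844942,"record_type":"fox_cub","group":4,"site":4},{"x":385.167130713122,"y":330.807188161676,"record_type":"fox_cub","group":4,"site":5}],"window":[0,1000,0,1000],"seed":2024}
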