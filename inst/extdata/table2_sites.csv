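# Per-site survey results and landscape composition for the 14 suburban fox
# study sites (plus badger densities at the three Brighton badger sites).
# Printed columns: area_km2 (survey area), n_response (questionnaire returns
# used), GS (green space km2 per km2), GA (garden area km2 per km2), HD
# (housing density, houses km-2), n_fox_records (fox cub records over 2
# years), fsd (city-level fox sightings density, per 1000 people km-2,
# repeated on each site row of the city), fgd (relative fox group density,
# groups km-2), bgd (relative badger group density, groups km-2; NA where
# badgers were not surveyed), houses_per_fox_group.
# n_fox_groups is DERIVED, not printed: fgd * area_km2 rounds to an exact
# integer at every site. IND and MG are not printed per site and are NA.
# colonisation: long_term = resident foxes before 1986, recent = after.
site_id,city,region,colonisation,area_km2,n_response,GS,GA,HD,n_fox_records,fsd,fgd,n_fox_groups,bgd,houses_per_fox_group,IND,MG
Croydon,London,Croydon,long_term,1.04,77,0.168,0.515,1093,45,703.1,3.84,4,NA,285,NA,NA
Surbiton,London,Surbiton,long_term,0.84,240,0.196,0.511,1614,232,703.1,2.39,2,NA,675,NA,NA
Elm Grove,Brighton,Elm Grove,long_term,1.18,752,0.126,0.281,4266,129,37.8,3.39,4,3.70,1260,NA,NA
Hove,Brighton,Hove,long_term,1.43,306,0.138,0.558,1155,120,37.8,3.49,5,2.67,331,NA,NA
Portslade,Brighton,Portslade,long_term,1.18,369,0.175,0.433,2149,137,37.8,4.25,5,0.87,506,NA,NA
Preston park,Brighton,Preston park,long_term,1.68,459,0.391,0.350,1104,256,37.8,2.98,5,NA,370,NA,NA
Bournemouth,Bournemouth,Bournemouth,long_term,0.92,366,0.085,0.536,1986,159,72.4,4.35,4,NA,457,NA,NA
Portsmouth,Portsmouth,Portsmouth,long_term,0.51,138,0.010,0.318,6028,21,13.2,3.91,2,NA,1540,NA,NA
Fenham,Newcastle,Fenham,recent,4.16,607,0.293,0.276,1907,38,51.2,1.68,7,NA,1133,NA,NA
Heaton,Newcastle,Heaton,recent,0.83,395,0.244,0.389,1770,48,51.2,4.81,4,NA,368,NA,NA
Almondbury,Huddersfield,Almondbury,recent,1.06,568,0.397,0.320,1530,337,14.6,4.73,5,NA,324,NA,NA
Lockwood,Huddersfield,Lockwood,recent,0.84,858,0.262,0.196,2118,253,14.6,3.57,3,NA,593,NA,NA
Norwich,Norwich,Norwich,recent,0.63,147,0.075,0.577,2087,19,36.6,4.73,3,NA,441,NA,NA
Preston,Preston,Preston,recent,0.72,363,0.138,0.528,2177,8,4.0,2.76,2,NA,789,NA,NA
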