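# Service score (I, 0-100) and sustainability score (S, whole percent) as
# reported for a four-tidal-flat Tokyo Bay assessment, evaluation year 2013.
# Sites: SN, UK (artificial), TR, OR (natural). S_pct is blank where the
# sustainability score was undefined (present status zero); site/service
# pairs omitted from that assessment are not listed.
service_id,site_id,I,S_pct
food,SN,12.4,-41
food,UK,5.3,17
food,TR,4.0,1
food,OR,5.6,12
coastal_protection,SN,81.2,0
coastal_protection,UK,96.4,13
coastal_protection,TR,85.1,-4
coastal_protection,OR,94.3,4
recreation,UK,78.7,-1
recreation,TR,0.3,-7
recreation,OR,0.3,16
environmental_education,SN,40.3,-41
environmental_education,UK,66.8,11
environmental_education,TR,0.0,
environmental_education,OR,39.4,17
research,SN,64.7,26
research,UK,14.5,2
research,TR,75.1,34
research,OR,70.8,48
historical_sites,TR,50.8,3
historical_sites,OR,80.0,13
rest_relaxation,UK,100,10
rest_relaxation,TR,3.2,-3
rest_relaxation,OR,2.8,17
suspended_removal,SN,100,18
suspended_removal,UK,20.7,13
suspended_removal,TR,14.3,9
suspended_removal,OR,8.9,10
organic_decomposition,SN,52.1,-8
organic_decomposition,UK,12.0,27
organic_decomposition,TR,40.2,22
organic_decomposition,OR,17.8,19
carbon_storage,SN,58.7,-9
carbon_storage,UK,16.6,-3
carbon_storage,TR,79.7,-8
carbon_storage,OR,13.6,3
diversity,SN,86.5,10
diversity,UK,100,28
diversity,TR,87.9,-2
diversity,OR,78.1,2
rare_species,SN,7.8,-14
rare_species,UK,12.0,16
rare_species,TR,100,54
rare_species,OR,100,31
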