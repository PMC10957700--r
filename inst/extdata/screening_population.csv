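region,year,ais,non_ais
rotterdam_presto,2018,522,445
amsterdam_ambulance,2018,623,634
amsterdam_ambulance,2019,712,704
amsterdam_ambulance,2020,853,643
amsterdam_ambulance,2021,797,591
amsterdam_ambulance,2022,554,369
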