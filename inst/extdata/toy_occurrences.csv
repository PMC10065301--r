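species,longitude,latitude
toy_species,101.25,21.75
toy_species,101.3,21.8
toy_species,101.25,22.25
toy_species,100.75,21.25
toy_species,100.75,21.75
toy_species,102.25,20.25
toy_species,101.75,20.75
toy_species,102.25,21.25
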