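sex,ethnicity,n
female,Asian,460
female,Black,155
female,Hispanic,415
female,Native American,15
female,South Asian,110
female,White,6057
male,Asian,637
male,Black,285
male,Hispanic,715
male,Native American,22
male,South Asian,389
male,White,11064
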