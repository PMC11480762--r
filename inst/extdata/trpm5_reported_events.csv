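protocol,voltage_mV,solution,species,valence,n_events,t_total_ns,opposing,reported_pS
compel,0,dicationic 135:15 mM,Na,1,0,900,FALSE,0
compel,0,dicationic 135:15 mM,Ca,2,0,900,FALSE,0
compel,0,dicationic 135:15 mM,Cl,-1,0,900,TRUE,0
compel,-50,dicationic 135:15 mM,Na,1,15,3000,FALSE,16
compel,-50,dicationic 135:15 mM,Ca,2,0,3000,FALSE,0
compel,-50,dicationic 135:15 mM,Cl,-1,0,3000,TRUE,0
compel,-130,dicationic 135:15 mM,Na,1,18,3000,FALSE,7
compel,-130,dicationic 135:15 mM,Ca,2,0,3000,FALSE,0
compel,-130,dicationic 135:15 mM,Cl,-1,0,3000,TRUE,0
compel,-380,dicationic 135:15 mM,Na,1,32,3000,FALSE,4
compel,-380,dicationic 135:15 mM,Ca,2,19,3000,FALSE,5
compel,-380,dicationic 135:15 mM,Cl,-1,1,3000,TRUE,0
compel,-610,dicationic 135:15 mM,Na,1,115,3000,FALSE,10
compel,-610,dicationic 135:15 mM,Ca,2,168,3000,FALSE,29
compel,-610,dicationic 135:15 mM,Cl,-1,6,3000,TRUE,-1
applied_field,-50,150 mM NaCl,Na,1,4,750,FALSE,19
applied_field,-50,150 mM CaCl2,Ca,2,0,750,FALSE,0
applied_field,-200,150 mM NaCl,Na,1,15,750,FALSE,17
applied_field,-200,150 mM CaCl2,Ca,2,4,750,FALSE,9
applied_field,-340,150 mM NaCl,Na,1,83,750,FALSE,52
applied_field,-340,150 mM KCl,K,1,34,750,FALSE,21
applied_field,-340,150 mM CaCl2,Ca,2,54,750,FALSE,85
f904t,-130,150 mM NaCl,Na,1,27,750,FALSE,NA
f904t,-130,150 mM CaCl2,Ca,2,13,750,FALSE,NA
f904t,-200,150 mM NaCl,Na,1,88,750,FALSE,NA
f904t,-200,150 mM CaCl2,Ca,2,28,750,FALSE,NA
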