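sample_id,organism,dry_biomass_g_per_L,biomass_sd,lipid_content_pct,lipid_sd
G4-3,Micractinium conductrix,1.34,0.05,62.63,8.32
G4-9,Micractinium conductrix,,,89.10,8.72
P2-15,Choricystis parasitica,0.18,0.04,57.48,3.19
P5-4,Monoraphidium sp.,1.30,0.15,66.72,4.52
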