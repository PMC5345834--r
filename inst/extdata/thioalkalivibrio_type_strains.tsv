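strain_id	species_name
AL2	Thioalkalivibrio versutus
ALM2	Thioalkalivibrio jannaschii
ALEN2	Thioalkalivibrio nitratireducens
ARh1	Thioalkalivibrio paradoxus
ARh2	Thioalkalivibrio thiocyanoxidans
ARhD1	Thioalkalivibrio thiocyanodenitrificans
ALJD	Thioalkalivibrio denitrificans
HL17	Thioalkalivibrio halophilus
HL-EbGr7	Thioalkalivibrio sulfidiphilus
ALJ12	Thioalkalivibrio nitratis
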