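molecule,brand,role,form,strength,dollars,units
insulin glargine,Lantus,originator,combined,combined,141135286,7328068
insulin glargine,Basaglar,biosimilar,combined,combined,9402061,619155
filgrastim,Neupogen,originator,combined,combined,204152590,1033508
filgrastim,Grastofil,biosimilar,combined,combined,62061576,382254
infliximab,Remicade,originator,combined,combined,2192819808,2190467
infliximab,Inflectra,biosimilar,combined,combined,37202503,67330
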