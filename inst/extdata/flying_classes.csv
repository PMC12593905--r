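taxon,class
Diptera,flying
Hymenoptera,flying
Formicidae,non_flying
Hemiptera,flying
Thysanoptera,flying
Coleoptera,flying
Lepidoptera,flying
Psocoptera,flying
Blattodea,flying
Orthoptera,flying
Trichoptera,flying
Neuroptera,flying
Ephemeroptera,flying
Collembola,non_flying
Zygentoma,non_flying
Acari,excluded
Araneae,excluded
Pseudoscorpiones,excluded
Isopoda,excluded
Myriapoda,excluded
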