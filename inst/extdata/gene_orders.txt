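# Signed circular mitochondrial gene orders (minus = N-strand).
# ancestral_insect: the putative ancestral insect arrangement.
# planthopper: the shared Delphacidae arrangement (trnC-trnW swapped,
#   nad6-trnP-trnT region reordered relative to the ancestor).
# sbph_prior: a previously published small brown planthopper annotation with
#   trnH between nad4L and nad6 rather than between nad5 and nad4.
ancestral_insect: trnI,-trnQ,trnM,nad2,trnW,-trnC,-trnY,cox1,trnL2,cox2,trnK,trnD,atp8,atp6,cox3,trnG,nad3,trnA,trnR,trnN,trnS1,trnE,-trnF,-nad5,-trnH,-nad4,-nad4L,trnT,-trnP,nad6,cob,trnS2,-nad1,-trnL1,-rrnL,-trnV,-rrnS
planthopper: trnI,-trnQ,trnM,nad2,-trnC,trnW,-trnY,cox1,trnL2,cox2,trnK,trnD,atp8,atp6,cox3,trnG,nad3,trnA,trnR,trnN,trnS1,trnE,-trnF,-nad5,-trnH,-nad4,-nad4L,nad6,-trnP,trnT,cob,trnS2,-nad1,-trnL1,-rrnL,-trnV,-rrnS
sbph_prior: trnI,-trnQ,trnM,nad2,-trnC,trnW,-trnY,cox1,trnL2,cox2,trnK,trnD,atp8,atp6,cox3,trnG,nad3,trnA,trnR,trnN,trnS1,trnE,-trnF,-nad5,-nad4,-nad4L,-trnH,nad6,-trnP,trnT,cob,trnS2,-nad1,-trnL1,-rrnL,-trnV,-rrnS
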