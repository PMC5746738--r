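# Default currency-metabolite exclusion list (compartment-free base names).
# Ubiquitous inorganic species whose shared production/consumption does not
# constitute a meaningful interaction between reactions.  Energy cofactors
# (atp, adp, nadh, nad, nadph, nadp, fadh2, fad, ...) are intentionally
# absent: cofactor-mediated coupling is what the analysis looks for.
h
h2o
pi
ppi
co2
o2
hco3
nh4
na1
k
cl
fe2
fe3
ca2
mg2
zn2
so4
h2o2
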