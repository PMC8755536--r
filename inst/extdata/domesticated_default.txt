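# Default exclusion list: widely domesticated mammals and wild ancestors.
# One binomial per line; override with your own curated list when analysing
# a real data extract.
Bos taurus
Bos indicus
Bos grunniens
Bubalus bubalis
Ovis aries
Ovis orientalis
Capra hircus
Capra aegagrus
Sus scrofa
Equus caballus
Equus ferus
Equus asinus
Equus africanus
Camelus bactrianus
Camelus dromedarius
Lama glama
Vicugna pacos
Canis lupus
Canis familiaris
Felis catus
Felis silvestris
Oryctolagus cuniculus
Cavia porcellus
Mustela putorius
Rattus norvegicus
Mus musculus
Mesocricetus auratus
Rangifer tarandus
Bos frontalis
Bos javanicus
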