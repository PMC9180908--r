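# Latent pollution-source membership used by the synthetic generator. Each source
# drives the listed parameters; parameters listed under no source receive purely
# idiosyncratic variation. The split mirrors the rotated-factor compositions of the
# field study the generator emulates: a geogenic weathering/ion-exchange source, a
# mixed geogenic-anthropogenic metal source, and an anthropogenic source.
source,parameter
geogenic,ph
geogenic,ec
geogenic,tds
geogenic,na
geogenic,hco3
geogenic,so4
geogenic,mn
geogenic,cd
geogenic,pb
mixed,ni
mixed,cr
mixed,cu
mixed,fe
anthropogenic,cl
anthropogenic,co
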