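# Effective single-value standards S_n for the Nemerow pollution index (NPI = C_n/S_n).
# Two entries differ from the screening guideline table: pH uses 8.5 (a single upper
# reference value, since NPI needs a ratio, not an interval) and HCO3 uses 300 mg/L
# (the desirable-level standard rather than the maximum permissible 500 mg/L).
parameter,standard
ph,8.5
ec,400
tds,1000
ca,100
mg,50
k,12
na,200
hco3,300
cl,250
so4,500
ni,3.0
mn,0.5
cr,0.05
cu,2.0
cd,0.05
pb,0.01
co,0.04
fe,0.3
zn,3.0
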