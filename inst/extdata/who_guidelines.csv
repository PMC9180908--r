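# Drinking-water guideline limits used for exceedance screening.
# Units match the measured parameter (ph dimensionless, ec in uS/cm, others mg/L).
# pH is interval-screened: a sample exceeds when outside [lower, limit].
parameter,lower,limit
ph,6.5,9.2
ec,NA,400
tds,NA,1000
ca,NA,100
mg,NA,50
k,NA,12
na,NA,200
hco3,NA,500
cl,NA,250
so4,NA,500
ni,NA,3.0
mn,NA,0.5
cr,NA,0.05
cu,NA,2.0
cd,NA,0.05
pb,NA,0.01
co,NA,0.04
fe,NA,0.3
zn,NA,3.0
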