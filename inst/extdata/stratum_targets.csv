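# Per-stratum distributional targets for the synthetic sample generator: the
# published per-stratum range (min-max) and mean +/- sd of every measured variable
# in the campaign the generator emulates (24 shallow, 14 mid-depth, 12 deep
# groundwater samples and 7 mine-water samples). Units: ph dimensionless, ec uS/cm,
# temp degC, depth m, all concentrations mg/L.
stratum,parameter,min,max,mean,sd
shallow,ph,7.2,8.3,7.6,0.3
shallow,ec,212,1288,738.9,263.0
shallow,temp,24.5,26.6,25.7,0.6
shallow,depth,25.0,40.0,35.5,4.3
shallow,tds,210,800,462.3,156.8
shallow,ca,27,100,40.8,15.4
shallow,mg,15.0,33.0,25.4,4.3
shallow,k,4.5,18.9,9.0,2.9
shallow,na,55,350,162.3,63.0
shallow,hco3,210,850,307.3,123.8
shallow,cl,80,150,114.2,20.2
shallow,so4,115,241,165.2,34.4
shallow,ni,0.05,0.53,0.25,0.14
shallow,mn,0.06,0.50,0.31,0.13
shallow,cr,0.03,0.15,0.09,0.04
shallow,cu,0.03,1.90,0.47,0.45
shallow,cd,0.01,0.31,0.07,0.08
shallow,pb,0.01,0.20,0.07,0.06
shallow,co,0.01,0.24,0.07,0.06
shallow,fe,0.23,1.34,0.86,0.38
shallow,zn,0.11,0.65,0.23,0.13
mid,ph,7.0,8.1,7.4,0.3
mid,ec,333,1030,674.2,212.1
mid,temp,24.6,27.2,25.6,0.6
mid,depth,41.0,80.0,56.2,13.0
mid,tds,210,635,412.9,126.9
mid,ca,34.0,85.0,54.8,15.9
mid,mg,18.0,37.0,29.5,5.8
mid,k,4.5,10.8,8.3,2.5
mid,na,45.0,170.0,94.3,42.4
mid,hco3,180,335,259.3,52.9
mid,cl,55.0,145.0,96.1,20.9
mid,so4,89.3,236.3,151.9,36.3
mid,ni,0.04,0.54,0.22,0.14
mid,mn,0.08,0.50,0.24,0.16
mid,cr,0.03,0.17,0.07,0.01
mid,cu,0.03,0.45,0.15,0.12
mid,cd,0.01,0.23,0.07,0.02
mid,pb,0.01,0.16,0.07,0.02
mid,co,0.03,0.23,0.09,0.03
mid,fe,0.24,1.56,0.70,0.51
mid,zn,0.12,0.37,0.22,0.07
deep,ph,7.2,8.1,7.5,0.2
deep,ec,469,1121,729.2,217.7
deep,temp,24.5,26.2,25.5,0.5
deep,depth,85.0,115.0,97.5,9.4
deep,tds,300,680,450.0,127.8
deep,ca,28.0,120.0,66.8,31.0
deep,mg,18.0,45.0,28.6,8.4
deep,k,0.9,10.8,6.1,3.4
deep,na,22.0,150.0,86.3,44.8
deep,hco3,190.0,330.0,263.3,45.2
deep,cl,80.0,135.0,103.8,16.3
deep,so4,78.8,152.3,128.3,23.1
deep,ni,0.03,0.40,0.18,0.13
deep,mn,0.08,0.35,0.23,0.10
deep,cr,0.01,0.08,0.04,0.02
deep,cu,0.01,0.24,0.11,0.08
deep,cd,0.01,0.06,0.04,0.01
deep,pb,0.01,0.04,0.02,0.01
deep,co,0.03,0.21,0.08,0.05
deep,fe,0.11,0.31,0.23,0.07
deep,zn,0.12,0.35,0.25,0.06
mine,ph,7.6,8.2,7.9,0.2
mine,ec,1650,1850,1801.8,69.3
mine,temp,24.1,27.8,26.0,1.3
mine,depth,24.0,35.0,28.7,4.2
mine,tds,1050,1280,1125.7,96.4
mine,ca,20.0,29.0,24.7,3.0
mine,mg,10.0,21.0,15.1,3.4
mine,k,1.8,12.0,5.7,3.9
mine,na,335,410,367.1,25.1
mine,hco3,610,680,651.4,27.9
mine,cl,80,120,94.3,15.4
mine,so4,325,350,337.0,8.8
mine,ni,0.32,0.52,0.41,0.08
mine,mn,0.65,1.58,1.15,0.33
mine,cr,0.19,0.30,0.24,0.04
mine,cu,1.20,2.25,1.50,0.40
mine,cd,0.35,0.48,0.41,0.05
mine,pb,0.25,0.58,0.43,0.12
mine,co,0.24,0.52,0.40,0.10
mine,fe,2.10,2.85,2.52,0.29
mine,zn,0.45,0.90,0.70,0.15
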