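# Oral toxicity values per element. rfd: oral reference dose (mg/kg-day);
# csf: cancer slope factor ((mg/kg-day)^-1). classification splits the element set
# into the non-carcinogenic (HQ) and carcinogenic (CR) branches of the assessment.
# RfDs for Ni, Mn, Cr, Cu, Cd, Pb, Zn are USEPA oral reference doses. The Co RfD and
# the slope factors are back-calculated from the reported risk table against the
# concentration extrema and are flagged low_confidence; Fe uses the conventional
# provisional 0.7 mg/kg-day (also low confidence).
element,rfd,csf,classification,confidence
ni,0.02,0.84,carcinogenic,low_confidence_csf
mn,0.14,NA,noncarcinogenic,reported
cr,1.5,0.5,carcinogenic,low_confidence_csf
cu,0.037,NA,noncarcinogenic,reported
cd,0.0005,15,carcinogenic,low_confidence_csf
pb,0.036,8.5,carcinogenic,low_confidence_csf
co,0.006,NA,noncarcinogenic,low_confidence_rfd
fe,0.7,NA,noncarcinogenic,low_confidence_rfd
zn,0.3,NA,noncarcinogenic,reported
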