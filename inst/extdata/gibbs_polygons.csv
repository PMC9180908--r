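# Default boundary polygons for the Gibbs diagram zones, in (ratio, log10 TDS mg/L)
# space. The conventional boomerang is not published with coordinates anywhere, so
# these are synthetic approximations of the standard envelope; override with a user
# file for a different convention. Vertices are listed in order per zone.
zone,ratio,log_tds
rock_weathering,0.00,1.95
rock_weathering,0.45,1.95
rock_weathering,0.75,2.30
rock_weathering,0.70,2.75
rock_weathering,0.40,3.00
rock_weathering,0.00,3.05
evaporation,0.40,3.00
evaporation,0.70,2.75
evaporation,0.90,3.00
evaporation,1.00,3.40
evaporation,1.00,4.80
evaporation,0.55,4.80
precipitation,0.40,0.70
precipitation,1.00,0.70
precipitation,1.00,1.90
precipitation,0.55,1.60
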