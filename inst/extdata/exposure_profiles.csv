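# Cohort-specific drinking-water exposure parameters for the intake model
# CDI = CW * ingestion_rate * EF * ED / (body_weight * AT).
# ingestion_rate in L/day, body_weight in kg, exposure_frequency in days/year,
# exposure_duration in years, averaging_time in days. With AT = 365 * ED the
# bracketed exposure factor EF*ED/AT equals 1 for both risk branches, i.e. no
# 30/70-year lifetime rescaling is applied to the carcinogenic branch. These
# values are back-calculated from the reported risk table (they are not tabulated
# with the survey) and can be overridden with a user file.
cohort,ingestion_rate,body_weight,exposure_frequency,exposure_duration,averaging_time
children,2,18,365,30,10950
male,3,65,365,30,10950
female,3,62,365,30,10950
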