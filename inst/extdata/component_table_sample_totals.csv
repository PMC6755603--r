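category,oral_eur,depot_eur,n
productivity_loss,57686.40,14220.00,132
ebm_services,41496.84,37775.82,132
goa_services,3780.70,1581.62,132
day_clinic_pia,16000.00,8400.00,132
ebm_inpatient,10344.07,3434.13,132
goa_inpatient,616.66,170.07,132
hospital_days,746168.65,170021.33,132
emergency_services,413.67,80.22,132
emergency_physician,1699.74,171.00,132
non_drug_interventions,49291.59,13699.69,132
depot_injections,0.00,306975.32,132
medication,323109.37,13642.75,132
comorbid_medication,60861.86,31425.42,132
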