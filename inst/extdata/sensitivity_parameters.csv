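name,mode,category,arm,base_mean,sd,min_value,max_value,base_unit_cost,min_cost,max_cost
productivity_loss_days,probability,productivity_loss,oral,40.06,29.62,10.44,69.68,,,
productivity_loss_days,probability,productivity_loss,depot,15.80,24.67,0.00,40.47,,,
day_clinic_days,probability,day_clinic_pia,oral,46.13,45.47,0.66,91.60,,,
day_clinic_days,probability,day_clinic_pia,depot,7.29,15.02,0.00,22.31,,,
hospital_days_occurrence,probability,hospital_days,oral,27.39,41.37,0.00,68.76,,,
hospital_days_occurrence,probability,hospital_days,depot,5.56,20.70,0.00,26.26,,,
emergency_physician_contacts,probability,emergency_physician,oral,1.42,0.79,0.00,2.21,,,
emergency_physician_contacts,probability,emergency_physician,depot,2.00,1.00,0.00,3.00,,,
emergency_service_contacts,probability,emergency_services,oral,2.38,2.53,0.00,4.91,,,
emergency_service_contacts,probability,emergency_services,depot,2.00,1.00,0.00,3.00,,,
day_clinic_cost,cost,day_clinic_pia,oral,46.13,,,,240,240,720
day_clinic_cost,cost,day_clinic_pia,depot,7.29,,,,240,240,720
hospital_day_cost,cost,hospital_days,oral,27.39,,,,,90,385
hospital_day_cost,cost,hospital_days,depot,5.56,,,,,90,385
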