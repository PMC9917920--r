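name,supply_impact,demand_impact,supply_targets,demand_targets,description
physician outreach,NA,0.15,,d_care_seeking;d_continuous;d_biologic,Physicians message at a practice level to their patients
system social signaling,NA,0.40,,d_care_seeking;d_continuous;d_biologic,Hospital systems reinforce confidence to their local area
national confidence building,NA,0.60,,d_care_seeking;d_continuous;d_biologic,Government messages at a societal level building confidence in care systems
simple navigation assistance,0.05,0.15,s_outpatient;s_procedures;s_biologic,d_care_seeking;d_continuous;d_biologic,Education-focused initiatives on navigating care after a disruption
barrier elimination,0.40,0.40,s_outpatient;s_procedures;s_biologic,d_care_seeking;d_continuous;d_biologic,Subsidized transportation when regular channels are unavailable
emergency response infrastructure,0.60,0.55,s_outpatient;s_procedures;s_biologic,d_care_seeking;d_continuous;d_biologic,Emergency care on demand when the normal setting is disrupted
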