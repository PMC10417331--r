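case_id,defect_label,comparison,difference_mm,percent
patient_01,Paprosky IIB,virtual_vs_model,-0.15,99.66
patient_02,Paprosky IIC,virtual_vs_model,-0.04,99.92
patient_03,Paprosky IIB,virtual_vs_model,-0.11,99.80
patient_04,Paprosky IIA,virtual_vs_model,-0.70,98.59
patient_05,Paprosky IIB,virtual_vs_model,-0.21,99.63
patient_06,Paprosky IIA,virtual_vs_model,0.05,100.09
patient_07,Paprosky IIC,virtual_vs_model,0.21,100.36
patient_08,Paprosky IIA,virtual_vs_model,-0.05,99.91
patient_09,Paprosky IIB,virtual_vs_model,-0.15,99.74
patient_10,Paprosky IIIA,virtual_vs_model,-0.03,99.94
patient_01,Paprosky IIB,model_vs_patient,0.25,100.56
patient_02,Paprosky IIC,model_vs_patient,0.10,100.19
patient_03,Paprosky IIB,model_vs_patient,0.16,100.30
patient_04,Paprosky IIA,model_vs_patient,1.50,103.12
patient_05,Paprosky IIB,model_vs_patient,0.81,101.45
patient_06,Paprosky IIA,model_vs_patient,0.51,100.93
patient_07,Paprosky IIC,model_vs_patient,0.40,99.32
patient_08,Paprosky IIA,model_vs_patient,0.14,99.76
patient_09,Paprosky IIB,model_vs_patient,0.04,99.93
patient_10,Paprosky IIIA,model_vs_patient,0.04,99.91
patient_01,Paprosky IIB,virtual_vs_patient,0.10,100.23
patient_02,Paprosky IIC,virtual_vs_patient,0.06,100.12
patient_03,Paprosky IIB,virtual_vs_patient,0.05,100.09
patient_04,Paprosky IIA,virtual_vs_patient,0.80,101.67
patient_05,Paprosky IIB,virtual_vs_patient,0.60,101.07
patient_06,Paprosky IIA,virtual_vs_patient,0.56,101.02
patient_07,Paprosky IIC,virtual_vs_patient,-0.19,99.67
patient_08,Paprosky IIA,virtual_vs_patient,-0.19,99.67
patient_09,Paprosky IIB,virtual_vs_patient,-0.19,99.68
patient_10,Paprosky IIIA,virtual_vs_patient,-0.07,99.85
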