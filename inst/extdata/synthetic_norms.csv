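staff_type,category,headcount
Biomedical scientist,CHPS,0.1
Biomedical scientist,HCA,0.25
Biomedical scientist,HCB,0.42
Biomedical scientist,PolyC,0.75
Biomedical scientist,PHA,1.25
Biomedical scientist,PHB,1.87
Biomedical scientist,PHC,2.49
Biomedical scientist,PHD,3.32
Biomedical scientist,RH,5.82
Biomedical scientist,EmTH,11.63
Biomedical scientist,EsTH,16.62
Community health nurse,CHPS,0.45
Community health nurse,HCA,1.07
Community health nurse,HCB,1.79
Community health nurse,PolyC,3.21
Community health nurse,PHA,5.36
Community health nurse,PHB,8.03
Community health nurse,PHC,10.71
Community health nurse,PHD,14.28
Community health nurse,RH,25
Community health nurse,EmTH,49.99
Community health nurse,EsTH,71.42
Critical care nurse,CHPS,0.43
Critical care nurse,HCA,1.04
Critical care nurse,HCB,1.73
Critical care nurse,PolyC,3.12
Critical care nurse,PHA,5.19
Critical care nurse,PHB,7.79
Critical care nurse,PHC,10.39
Critical care nurse,PHD,13.85
Critical care nurse,RH,24.24
Critical care nurse,EmTH,48.48
Critical care nurse,EsTH,69.26
Dental surgeon,CHPS,0
Dental surgeon,HCA,0
Dental surgeon,HCB,0
Dental surgeon,PolyC,0
Dental surgeon,PHA,0.77
Dental surgeon,PHB,1.15
Dental surgeon,PHC,1.54
Dental surgeon,PHD,2.05
Dental surgeon,RH,3.59
Dental surgeon,EmTH,7.18
Dental surgeon,EsTH,10.25
Emergency nurse,CHPS,0.49
Emergency nurse,HCA,1.17
Emergency nurse,HCB,1.94
Emergency nurse,PolyC,3.5
Emergency nurse,PHA,5.83
Emergency nurse,PHB,8.74
Emergency nurse,PHC,11.66
Emergency nurse,PHD,15.54
Emergency nurse,RH,27.2
Emergency nurse,EmTH,54.4
Emergency nurse,EsTH,77.71
Enrolled nurse,CHPS,0.32
Enrolled nurse,HCA,0.76
Enrolled nurse,HCB,1.27
Enrolled nurse,PolyC,2.29
Enrolled nurse,PHA,3.81
Enrolled nurse,PHB,5.72
Enrolled nurse,PHC,7.62
Enrolled nurse,PHD,10.16
Enrolled nurse,RH,17.78
Enrolled nurse,EmTH,35.57
Enrolled nurse,EsTH,50.81
Family medicine physician,CHPS,0
Family medicine physician,HCA,0
Family medicine physician,HCB,0
Family medicine physician,PolyC,0
Family medicine physician,PHA,0.86
Family medicine physician,PHB,1.29
Family medicine physician,PHC,1.72
Family medicine physician,PHD,2.29
Family medicine physician,RH,4
Family medicine physician,EmTH,8.01
Family medicine physician,EsTH,11.44
General surgeon,CHPS,0
General surgeon,HCA,0
General surgeon,HCB,0
General surgeon,PolyC,0
General surgeon,PHA,0.43
General surgeon,PHB,0.65
General surgeon,PHC,0.86
General surgeon,PHD,1.15
General surgeon,RH,2.01
General surgeon,EmTH,4.02
General surgeon,EsTH,5.75
Medical officer (general practitioner),CHPS,0
Medical officer (general practitioner),HCA,0
Medical officer (general practitioner),HCB,0
Medical officer (general practitioner),PolyC,0
Medical officer (general practitioner),PHA,0.26
Medical officer (general practitioner),PHB,0.38
Medical officer (general practitioner),PHC,0.51
Medical officer (general practitioner),PHD,0.68
Medical officer (general practitioner),RH,1.19
Medical officer (general practitioner),EmTH,2.38
Medical officer (general practitioner),EsTH,3.41
Mental health nurse,CHPS,0.1
Mental health nurse,HCA,0.25
Mental health nurse,HCB,0.42
Mental health nurse,PolyC,0.75
Mental health nurse,PHA,1.25
Mental health nurse,PHB,1.88
Mental health nurse,PHC,2.51
Mental health nurse,PHD,3.34
Mental health nurse,RH,5.85
Mental health nurse,EmTH,11.7
Mental health nurse,EsTH,16.71
Midwife,CHPS,0.14
Midwife,HCA,0.35
Midwife,HCB,0.58
Midwife,PolyC,1.04
Midwife,PHA,1.73
Midwife,PHB,2.6
Midwife,PHC,3.47
Midwife,PHD,4.62
Midwife,RH,8.09
Midwife,EmTH,16.18
Midwife,EsTH,23.12
Obstetrician & gynaecologist,CHPS,0
Obstetrician & gynaecologist,HCA,0
Obstetrician & gynaecologist,HCB,0
Obstetrician & gynaecologist,PolyC,0
Obstetrician & gynaecologist,PHA,0.54
Obstetrician & gynaecologist,PHB,0.81
Obstetrician & gynaecologist,PHC,1.08
Obstetrician & gynaecologist,PHD,1.45
Obstetrician & gynaecologist,RH,2.53
Obstetrician & gynaecologist,EmTH,5.06
Obstetrician & gynaecologist,EsTH,7.23
Ophthalmic nurse,CHPS,0.08
Ophthalmic nurse,HCA,0.18
Ophthalmic nurse,HCB,0.3
Ophthalmic nurse,PolyC,0.55
Ophthalmic nurse,PHA,0.91
Ophthalmic nurse,PHB,1.36
Ophthalmic nurse,PHC,1.82
Ophthalmic nurse,PHD,2.43
Ophthalmic nurse,RH,4.25
Ophthalmic nurse,EmTH,8.49
Ophthalmic nurse,EsTH,12.13
Ophthalmologist,CHPS,0
Ophthalmologist,HCA,0
Ophthalmologist,HCB,0
Ophthalmologist,PolyC,0
Ophthalmologist,PHA,1
Ophthalmologist,PHB,1.5
Ophthalmologist,PHC,2.01
Ophthalmologist,PHD,2.67
Ophthalmologist,RH,4.68
Ophthalmologist,EmTH,9.36
Ophthalmologist,EsTH,13.37
Paediatrician,CHPS,0
Paediatrician,HCA,0
Paediatrician,HCB,0
Paediatrician,PolyC,0
Paediatrician,PHA,0.87
Paediatrician,PHB,1.3
Paediatrician,PHC,1.74
Paediatrician,PHD,2.32
Paediatrician,RH,4.05
Paediatrician,EmTH,8.1
Paediatrician,EsTH,11.58
Pharmacist,CHPS,0.35
Pharmacist,HCA,0.85
Pharmacist,HCB,1.42
Pharmacist,PolyC,2.55
Pharmacist,PHA,4.25
Pharmacist,PHB,6.38
Pharmacist,PHC,8.51
Pharmacist,PHD,11.35
Pharmacist,RH,19.86
Pharmacist,EmTH,39.71
Pharmacist,EsTH,56.73
Pharmacy technician,CHPS,0.33
Pharmacy technician,HCA,0.78
Pharmacy technician,HCB,1.31
Pharmacy technician,PolyC,2.35
Pharmacy technician,PHA,3.92
Pharmacy technician,PHB,5.87
Pharmacy technician,PHC,7.83
Pharmacy technician,PHD,10.44
Pharmacy technician,RH,18.28
Pharmacy technician,EmTH,36.55
Pharmacy technician,EsTH,52.22
Physician assistant (anaesthesia),CHPS,0
Physician assistant (anaesthesia),HCA,0
Physician assistant (anaesthesia),HCB,0
Physician assistant (anaesthesia),PolyC,0
Physician assistant (anaesthesia),PHA,0.6
Physician assistant (anaesthesia),PHB,0.9
Physician assistant (anaesthesia),PHC,1.19
Physician assistant (anaesthesia),PHD,1.59
Physician assistant (anaesthesia),RH,2.79
Physician assistant (anaesthesia),EmTH,5.57
Physician assistant (anaesthesia),EsTH,7.96
Physician assistant (medical),CHPS,0
Physician assistant (medical),HCA,0
Physician assistant (medical),HCB,0
Physician assistant (medical),PolyC,0
Physician assistant (medical),PHA,1.45
Physician assistant (medical),PHB,2.17
Physician assistant (medical),PHC,2.89
Physician assistant (medical),PHD,3.86
Physician assistant (medical),RH,6.75
Physician assistant (medical),EmTH,13.5
Physician assistant (medical),EsTH,19.29
Public health nurse,CHPS,0.39
Public health nurse,HCA,0.94
Public health nurse,HCB,1.56
Public health nurse,PolyC,2.81
Public health nurse,PHA,4.69
Public health nurse,PHB,7.03
Public health nurse,PHC,9.37
Public health nurse,PHD,12.5
Public health nurse,RH,21.87
Public health nurse,EmTH,43.74
Public health nurse,EsTH,62.49
Radiographer/x-ray technician,CHPS,0.1
Radiographer/x-ray technician,HCA,0.23
Radiographer/x-ray technician,HCB,0.39
Radiographer/x-ray technician,PolyC,0.7
Radiographer/x-ray technician,PHA,1.16
Radiographer/x-ray technician,PHB,1.74
Radiographer/x-ray technician,PHC,2.32
Radiographer/x-ray technician,PHD,3.09
Radiographer/x-ray technician,RH,5.41
Radiographer/x-ray technician,EmTH,10.82
Radiographer/x-ray technician,EsTH,15.46
Registered general nurse,CHPS,0.12
Registered general nurse,HCA,0.29
Registered general nurse,HCB,0.49
Registered general nurse,PolyC,0.87
Registered general nurse,PHA,1.46
Registered general nurse,PHB,2.19
Registered general nurse,PHC,2.91
Registered general nurse,PHD,3.89
Registered general nurse,RH,6.8
Registered general nurse,EmTH,13.6
Registered general nurse,EsTH,19.43
Technical officer (laboratory),CHPS,0.15
Technical officer (laboratory),HCA,0.37
Technical officer (laboratory),HCB,0.61
Technical officer (laboratory),PolyC,1.1
Technical officer (laboratory),PHA,1.84
Technical officer (laboratory),PHB,2.76
Technical officer (laboratory),PHC,3.68
Technical officer (laboratory),PHD,4.9
Technical officer (laboratory),RH,8.58
Technical officer (laboratory),EmTH,17.15
Technical officer (laboratory),EsTH,24.5
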