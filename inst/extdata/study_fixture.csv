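"facility_id","district","facility_type","x","y","assessed","refers_to","running_water","decontamination_buckets","safety_boxes","soap","removal_days_per_week","n_trained_removal","n_trained_ultrasound","syringes","local_anesthetic","sterile_band_aids","scalpel_with_blade","curved_forceps","straight_forceps","antiseptic","cotton_balls","sterile_gauze","vasectomy_forceps","ultrasound_machine","sterile_towels","examination_table","sterile_surgical_drape","sterile_equipment_tray","autoclave"
"DK-HC-01","DAKAR_CENTRE","HEALTH_CENTER_I",2000,2000,TRUE,NA,1,1,1,1,7,2,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1
"DK-HC-02","DAKAR_CENTRE","HEALTH_CENTER_I",2800,2000,TRUE,NA,1,1,1,1,7,2,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1
"DK-HC-03","DAKAR_CENTRE","HEALTH_CENTER_I",3600,2000,TRUE,NA,1,1,1,1,7,2,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1
"DK-HC-04","DAKAR_CENTRE","HEALTH_CENTER_I",4400,2000,TRUE,"DK-HC-01",1,1,1,1,7,2,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1
"DK-HC-05","DAKAR_CENTRE","HEALTH_CENTER_I",2000,2800,TRUE,"DK-HC-01",1,1,1,1,7,2,0,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1
"DK-HC-06","DAKAR_CENTRE","HEALTH_CENTER_I",2800,2800,TRUE,"DK-HC-01",1,1,1,1,7,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"DK-HP-01","DAKAR_CENTRE","HEALTH_POST",3600,2800,TRUE,NA,1,1,1,1,5,1,0,0,1,0,0,0,1,1,1,1,0,0,1,1,0,1,0
"DK-HP-02","DAKAR_CENTRE","HEALTH_POST",4400,2800,TRUE,NA,1,1,1,1,5,1,0,1,1,1,1,1,1,1,1,0,1,0,1,1,0,1,0
"DK-HP-03","DAKAR_CENTRE","HEALTH_POST",2000,3600,TRUE,NA,1,1,1,1,5,1,0,0,1,0,0,0,1,1,1,1,0,0,0,1,0,1,0
"DK-HP-04","DAKAR_CENTRE","HEALTH_POST",2800,3600,TRUE,NA,1,1,1,1,5,1,0,1,0,1,1,1,0,1,1,1,0,0,0,1,0,1,0
"DK-HP-05","DAKAR_CENTRE","HEALTH_POST",3600,3600,TRUE,"DK-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"DK-HP-06","DAKAR_CENTRE","HEALTH_POST",4400,3600,TRUE,"DK-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,0,0,1,1,1,1,1
"DK-HP-07","DAKAR_CENTRE","HEALTH_POST",2000,4400,TRUE,"DK-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,0,0,1,1,0,1,1
"KD-HC-01","KOLDA","HEALTH_CENTER_II",3000,2000,TRUE,NA,1,1,1,1,7,2,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1
"KD-HP-01","KOLDA","HEALTH_POST",8000,2000,TRUE,"KD-HOSP-01",1,1,1,1,5,2,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1
"KD-HP-02","KOLDA","HEALTH_POST",13000,2000,TRUE,"KD-HOSP-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-03","KOLDA","HEALTH_POST",18000,2000,TRUE,"KD-HOSP-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-04","KOLDA","HEALTH_POST",23000,2000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-05","KOLDA","HEALTH_POST",3000,7000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-06","KOLDA","HEALTH_POST",8000,7000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-07","KOLDA","HEALTH_POST",13000,7000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-08","KOLDA","HEALTH_POST",18000,7000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-09","KOLDA","HEALTH_POST",23000,7000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-10","KOLDA","HEALTH_POST",3000,12000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-11","KOLDA","HEALTH_POST",8000,12000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-12","KOLDA","HEALTH_POST",13000,12000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-13","KOLDA","HEALTH_POST",18000,12000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1
"KD-HP-14","KOLDA","HEALTH_POST",23000,12000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,0,1,0
"KD-HP-15","KOLDA","HEALTH_POST",3000,17000,TRUE,"KD-HC-01",1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,1,0,1,1,0,1,0
"KD-HP-16","KOLDA","HEALTH_POST",8000,17000,TRUE,"KD-HC-01",0,1,1,1,5,1,0,1,1,1,1,1,1,1,1,1,0,1,1,1,0,1,0
"KD-HP-17","KOLDA","HEALTH_POST",13000,17000,TRUE,"KD-HC-01",0,1,1,1,5,1,0,1,1,1,1,1,1,1,1,1,0,0,0,1,0,1,0
"KD-HP-18","KOLDA","HEALTH_POST",18000,17000,TRUE,"KD-HC-01",0,1,1,1,5,1,0,1,1,1,1,1,1,1,1,1,0,0,0,1,0,1,0
"KD-HP-19","KOLDA","HEALTH_POST",23000,17000,TRUE,"KD-HC-01",1,1,1,1,5,1,0,0,1,1,1,1,1,1,1,1,0,0,0,1,0,1,0
"KD-HP-20","KOLDA","HEALTH_POST",3000,22000,TRUE,"KD-HC-01",1,1,1,1,5,1,0,1,0,1,0,1,1,1,1,1,0,0,0,1,0,1,0
"KD-HP-21","KOLDA","HEALTH_POST",8000,22000,TRUE,"KD-HC-01",1,1,1,1,5,1,0,1,0,1,0,1,1,1,1,1,0,0,0,1,0,1,0
"KD-HP-22","KOLDA","HEALTH_POST",13000,22000,TRUE,"KD-HC-01",1,1,1,1,5,1,0,1,1,0,1,1,1,1,1,1,0,0,0,1,0,1,0
"KD-HP-23","KOLDA","HEALTH_POST",18000,22000,TRUE,NA,1,1,1,1,5,1,0,1,1,1,1,1,0,1,1,1,0,0,0,1,0,1,0
"KD-HP-24","KOLDA","HEALTH_POST",23000,22000,TRUE,NA,1,1,1,1,5,2,1,1,1,1,1,1,1,1,1,1,0,0,1,1,1,1,1
"KD-HP-25","KOLDA","HEALTH_POST",3000,27000,TRUE,NA,1,1,1,1,5,2,0,1,1,1,1,1,1,1,1,1,0,0,1,1,0,1,1
"KD-HOSP-01","KOLDA","HOSPITAL",24500,23500,FALSE,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
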