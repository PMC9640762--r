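{"general_items":["running_water","decontamination_buckets","safety_boxes","soap"],"min_days_per_week":5,"hr_regular_min_removal_trained":1,"hr_difficult_min_ultrasound_trained":1,"equipment_regular":["syringes","local_anesthetic","sterile_band_aids","scalpel_with_blade","curved_forceps","straight_forceps"],"equipment_any_of":["sterile_gauze",["antiseptic","cotton_balls"]],"equipment_difficult_extra":["vasectomy_forceps","ultrasound_machine","sterile_towels","examination_table","sterile_surgical_drape","sterile_equipment_tray"],"gauze_rule":"gauze_or_antiseptic_cotton"}
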