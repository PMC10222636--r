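lab,recording,ontology_id,term_label,granular_group,general_group
Lab_A,Yolk_opacity,ZP:0002198,"yolk opaque, abnormal",,
Lab_A,Presence_of_head_Edema,ZP:SYN0001,"head edematous, abnormal",head edema,head defects
Lab_A,Smaller_abnormal_eye_shape,ZP:SYN0002,"eye decreased size, abnormal",eye defects,head defects
Lab_A,Smaller_abnormal_head_shape,ZP:SYN0003,"snout malformed, abnormal",snout defects,head defects
Lab_A,Jaw_malformed,ZP:SYN0004,"ventral mandibular arch morphology, abnormal",jaw defects,head defects
Lab_A,Curved_axis,ZP:SYN0005,"axis curved, abnormal",axis defects,torso defects
Lab_A,Notochord_abnormal,ZP:SYN0006,"notochord morphology, abnormal",notochord defects,torso defects
Lab_A,Pericardial_edema,ZP:SYN0007,"heart edematous, abnormal",heart edema,heart defects
Lab_A,Yolk_sac_edema,ZP:SYN0008,"yolk edematous, abnormal",yolk edema,yolk defects
Lab_A,Delayed_hatching,ZP:SYN0009,"hatching delayed, abnormal",hatching defects,hatching defects
Lab_A,Pectoral_fin_missing,ZP:SYN0010,"pectoral fin absent, abnormal",pectoral fin defects,fin defects
Lab_A,Caudal_fin_malformed,ZP:SYN0011,"caudal fin morphology, abnormal",caudal fin defects,fin defects
Lab_B,EDEM,ZP:SYN0007,"heart edematous, abnormal",heart edema,heart defects
Lab_B,EDEM,ZP:SYN0008,"yolk edematous, abnormal",yolk edema,yolk defects
Lab_B,BRN_,ZP:SYN0003,"snout malformed, abnormal",snout defects,head defects
Lab_B,BRN_,ZP:SYN0010,"pectoral fin absent, abnormal",pectoral fin defects,fin defects
Lab_B,LTRK,ZP:SYN0005,"axis curved, abnormal",axis defects,torso defects
Lab_B,LTRK,ZP:SYN0006,"notochord morphology, abnormal",notochord defects,torso defects
Lab_B,LTRK,ZP:SYN0011,"caudal fin morphology, abnormal",caudal fin defects,fin defects
Lab_B,EYE_,ZP:SYN0002,"eye decreased size, abnormal",eye defects,head defects
Lab_B,JAW_,ZP:SYN0004,"ventral mandibular arch morphology, abnormal",jaw defects,head defects
Lab_B,HTCH,ZP:SYN0009,"hatching delayed, abnormal",hatching defects,hatching defects
Lab_B,NECR,ZP:SYN0012,"whole organism dead, abnormal",,
Lab_B,TCHR,ZP:SYN0013,"touch response decreased, abnormal",,
Lab_C,Pericardial_tissue__Edema,ZP:SYN0007,"heart edematous, abnormal",heart edema,heart defects
Lab_C,Yolk_sac__Edema,ZP:SYN0008,"yolk edematous, abnormal",yolk edema,yolk defects
Lab_C,Eye_size__decreased,ZP:SYN0002,"eye decreased size, abnormal",eye defects,head defects
Lab_C,Snout__malformed,ZP:SYN0003,"snout malformed, abnormal",snout defects,head defects
Lab_C,Jaw__malformed,ZP:SYN0004,"ventral mandibular arch morphology, abnormal",jaw defects,head defects
Lab_C,Axis__curved,ZP:SYN0005,"axis curved, abnormal",axis defects,torso defects
Lab_C,Notochord__abnormal,ZP:SYN0006,"notochord morphology, abnormal",notochord defects,torso defects
Lab_C,Hatching__delayed,ZP:SYN0009,"hatching delayed, abnormal",hatching defects,hatching defects
Lab_C,Pigment__abnormal,ZP:SYN0014,"pigmentation abnormal",pigment defects,abnormal pigmentation
Lab_C,necrosis,ZP:SYN0012,"whole organism dead, abnormal",,
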