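case_label,drug,sex,age_band,indication,history,combined_drugs,onset_band,symptoms,nadir_plt_band,plt_decrease_band,anti_pf4,four_t_band,d_dimer_elevated,liver_kidney_abnormal,treatments,alt_anticoagulants,recovery_band,outcome
case01,enoxaparin,male,18-60,joint_operation,none,none,5-10,thrombus;skin_lesions;fever,20-49,>50,positive,6-8,,TRUE,withdrawal;emergency,fondaparinux;rivaroxaban,5-10,recovery
case02,enoxaparin,male,>60,fracture,obesity,,>10,thrombus;hemorrhage,50-100,>50,positive,,,,withdrawal,lepirudin,>10,recovery
case03,enoxaparin,female,>60,traffic_accident,none,none,5-10,thrombus;dyspnea,20-49,>50,positive,6-8,,,withdrawal,fondaparinux,5-10,recovery
case04,enoxaparin,male,>60,embolism,tumor,antidiabetic,5-10,skin_lesions;cerebral_infarction,>100,>50,positive,,TRUE,,withdrawal,none,,recovery
case05,enoxaparin,male,18-60,traffic_accident,hypertension,none,5-10,thrombus;limb_necrosis,50-100,>50,,,FALSE,,withdrawal,argatroban,5-10,recovery
case06,enoxaparin,female,>60,embolism,none,none,5-10,thrombus;skin_lesions;heart_failure,>100,>50,,,,,withdrawal;surgical_thrombectomy,fondaparinux;acenocoumarol,5-10,recovery
case07,enoxaparin,female,>60,embolism,none,none,5-10,thrombus;hemorrhage,50-100,>50,positive,,,TRUE,withdrawal,argatroban,<5,recovery
case08,enoxaparin,female,>60,infection,tumor,none,5-10,skin_lesions;cerebral_infarction,20-49,>50,,6-8,,TRUE,withdrawal,warfarin,<5,recovery
case09,enoxaparin,female,>60,heart_failure,none,antidiabetic,>10,thrombus;limb_necrosis,50-100,30-50,positive,,,,withdrawal,argatroban,5-10,recovery
case10,enoxaparin,female,18-60,dialysis,hypertension,none,5-10,thrombus;limb_necrosis,50-100,>50,positive,6-8,,,withdrawal,argatroban,,recovery
case11,enoxaparin,female,>60,joint_operation,none,none,>10,skin_lesions;cerebral_infarction,20-49,>50,positive,,,,withdrawal,warfarin,5-10,recovery
case12,enoxaparin,female,>60,joint_operation,obesity,none,5-10,thrombus;hemorrhage,20-49,>50,positive,,,,withdrawal,lepirudin,,recovery
case13,enoxaparin,female,>60,tumor,hypertension,antihypertensive;other_anticoagulant,<5,thrombus;hemorrhage,20-49,>50,positive,,,,withdrawal,argatroban,5-10,death
case14,enoxaparin,male,>60,heart_failure,surgery,antihypertensive;antibiotics,5-10,thrombus;dyspnea,>100,>50,,,,,withdrawal,none,5-10,recovery
case15,enoxaparin,female,>60,surgery,obesity,none,5-10,thrombus;hemorrhage,50-100,>50,positive,,,,withdrawal,lepirudin,5-10,recovery
case16,enoxaparin,female,>60,joint_operation,tumor,none,5-10,skin_lesions;cerebral_infarction,10-19,>50,positive,4-5,,FALSE,withdrawal,warfarin,,recovery
case17,enoxaparin,female,>60,dialysis,none,none,>10,thrombus;dyspnea,20-49,>50,positive,,TRUE,,withdrawal,fondaparinux;apixaban,<5,recovery
case18,enoxaparin,female,18-60,fracture,diabetes;immune_related,none,<5,thrombus;dyspnea,>100,>50,positive,,FALSE,,withdrawal,fondaparinux;rivaroxaban,,recovery
case19,enoxaparin,female,18-60,embolism;pregnancy,diabetes;tumor,none,5-10,thrombus;skin_lesions;heart_failure,50-100,>50,positive,,TRUE,TRUE,withdrawal;surgical_thrombectomy,fondaparinux;warfarin,5-10,recovery
case20,enoxaparin,female,>60,fracture,diabetes;thrombus_history,none,<5,thrombus;dyspnea,20-49,30-50,positive,6-8,,FALSE,withdrawal,fondaparinux;apixaban,5-10,recovery
case21,enoxaparin,female,>60,joint_operation,diabetes;myocardial_disease,none,>10,thrombus;skin_lesions;acute_renal_failure,>100,>50,positive,6-8,FALSE,,withdrawal;surgical_thrombectomy,none,>10,recovery
case22,nadroparin,female,>60,dialysis,surgery,antihypertensive;antibiotics,5-10,thrombus;dyspnea,20-49,>50,,6-8,TRUE,,withdrawal,fondaparinux;clopidogrel,<5,recovery
case23,nadroparin,male,18-60,tumor,obesity,none,5-10,thrombus;hemorrhage,>100,>50,positive,,,,withdrawal,lepirudin,5-10,recovery
case24,nadroparin,female,>60,infection,diabetes;myocardial_disease,none,5-10,thrombus;skin_lesions,<10,,positive,6-8,,,withdrawal;thrombolytic,fondaparinux;rivaroxaban,5-10,recovery
case25,nadroparin,male,>60,heart_failure,diabetes;cholecystectomy,none,>10,thrombus;skin_lesions,50-100,,positive,,,FALSE,withdrawal;glucocorticoid,none,<5,recovery
case26,nadroparin,female,18-60,joint_operation,none,antihypertensive;chemotherapeutic,5-10,thrombus;hemorrhage,20-49,,positive,6-8,,,withdrawal,lepirudin,>10,recovery
case27,nadroparin,female,18-60,embolism,none,none,5-10,thrombus;skin_lesions;shock,50-100,,positive,6-8,,,withdrawal;platelet_transfusion,fondaparinux;rivaroxaban,,recovery
case28,nadroparin,female,18-60,fracture,hypertension,none,<5,thrombus;cerebral_infarction,50-100,>50,,6-8,,,withdrawal,warfarin,<5,recovery
case29,nadroparin,female,>60,joint_operation,diabetes;chronic_renal_insufficiency,none,5-10,thrombus;skin_lesions;heart_failure,10-19,>50,positive,6-8,FALSE,,withdrawal;surgical_thrombectomy,fondaparinux;acenocoumarol,>10,recovery
case30,nadroparin,female,18-60,surgery,surgery,none,5-10,thrombus;dyspnea,,30-50,positive,,FALSE,,withdrawal,lepirudin,>10,recovery
case31,nadroparin,female,18-60,embolism,surgery,none,>10,thrombus;dyspnea,,>50,positive,6-8,,,withdrawal,lepirudin,>10,recovery
case32,nadroparin,male,>60,surgery,diabetes;myocardial_disease,none,>10,thrombus;skin_lesions;acute_renal_failure,50-100,>50,positive,6-8,FALSE,,withdrawal;platelet_transfusion,fondaparinux;acenocoumarol,>10,recovery
case33,nadroparin,female,>60,embolism,surgery,none,5-10,thrombus;dyspnea,>100,,positive,,,TRUE,withdrawal,lepirudin,5-10,recovery
case34,nadroparin,female,18-60,joint_operation,surgery,none,5-10,thrombus;dyspnea,,>50,positive,,,,withdrawal,fondaparinux,<5,recovery
case35,nadroparin,male,18-60,embolism,hypertension,none,5-10,thrombus;limb_necrosis,50-100,>50,positive,6-8,,,withdrawal,argatroban,5-10,recovery
case36,dalteparin,male,>60,joint_operation,diabetes;chronic_renal_insufficiency,none,>10,thrombus;skin_lesions;heart_failure,>100,,positive,4-5,,,withdrawal;surgical_thrombectomy,fondaparinux;acenocoumarol,<5,recovery
case37,dalteparin,female,>60,surgery,obesity,none,>10,thrombus;hemorrhage,10-19,>50,positive,,,,withdrawal,lepirudin,,recovery
case38,dalteparin,female,>60,dialysis,diabetes;chronic_renal_insufficiency,none,>10,thrombus;skin_lesions;heart_failure,20-49,>50,positive,,,,withdrawal;surgical_thrombectomy,fondaparinux;acenocoumarol,,recovery
case39,dalteparin,male,18-60,fracture,obesity,none,>10,thrombus;hemorrhage,50-100,>50,positive,4-5,,,withdrawal,lepirudin,<5,recovery
case40,tinzaparin,female,>60,embolism,hypertension,none,<5,thrombus;limb_necrosis,20-49,<30,positive,6-8,,,withdrawal,argatroban,5-10,recovery
case41,tinzaparin,female,18-60,embolism,surgery,none,>10,thrombus;dyspnea,>100,>50,,,,,withdrawal,fondaparinux;dabigatran,,recovery
case42,bemiparin,male,>60,surgery,surgery,none,5-10,thrombus;dyspnea,20-49,>50,positive,6-8,,,withdrawal,lepirudin,>10,recovery
case43,bemiparin,female,<18,tumor,surgery,none,>10,thrombus;dyspnea,50-100,>50,positive,6-8,TRUE,,withdrawal,fondaparinux,5-10,worse
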