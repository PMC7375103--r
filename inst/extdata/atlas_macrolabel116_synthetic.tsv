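label	hemisphere	voxel_count
Precentral_L	L	647
Precentral_R	R	354
Frontal_Sup_L	L	1568
Frontal_Sup_R	R	1001
Frontal_Sup_Orb_L	L	460
Frontal_Sup_Orb_R	R	487
Frontal_Mid_L	L	499
Frontal_Mid_R	R	881
Frontal_Mid_Orb_L	L	321
Frontal_Mid_Orb_R	R	551
Frontal_Inf_Oper_L	L	510
Frontal_Inf_Oper_R	R	613
Frontal_Inf_Tri_L	L	763
Frontal_Inf_Tri_R	R	611
Frontal_Inf_Orb_L	L	303
Frontal_Inf_Orb_R	R	306
Rolandic_Oper_L	L	365
Rolandic_Oper_R	R	221
Supp_Motor_Area_L	L	369
Supp_Motor_Area_R	R	361
Olfactory_L	L	328
Olfactory_R	R	596
Frontal_Sup_Medial_L	L	405
Frontal_Sup_Medial_R	R	750
Frontal_Med_Orb_L	L	397
Frontal_Med_Orb_R	R	932
Rectus_L	L	476
Rectus_R	R	594
Insula_L	L	525
Insula_R	R	766
Cingulum_Ant_L	L	561
Cingulum_Ant_R	R	508
Cingulum_Mid_L	L	388
Cingulum_Mid_R	R	225
Cingulum_Post_L	L	604
Cingulum_Post_R	R	610
Hippocampus_L	L	299
Hippocampus_R	R	357
ParaHippocampal_L	L	360
ParaHippocampal_R	R	618
Amygdala_L	L	650
Amygdala_R	R	513
Calcarine_L	L	332
Calcarine_R	R	291
Cuneus_L	L	480
Cuneus_R	R	701
Lingual_L	L	713
Lingual_R	R	727
Occipital_Sup_L	L	647
Occipital_Sup_R	R	764
Occipital_Mid_L	L	229
Occipital_Mid_R	R	1187
Occipital_Inf_L	L	483
Occipital_Inf_R	R	544
Fusiform_L	L	486
Fusiform_R	R	363
Postcentral_L	L	362
Postcentral_R	R	441
Parietal_Sup_L	L	821
Parietal_Sup_R	R	309
Parietal_Inf_L	L	801
Parietal_Inf_R	R	523
SupraMarginal_L	L	607
SupraMarginal_R	R	452
Angular_L	L	316
Angular_R	R	843
Precuneus_L	L	442
Precuneus_R	R	473
Paracentral_Lobule_L	L	777
Paracentral_Lobule_R	R	231
Caudate_L	L	326
Caudate_R	R	353
Putamen_L	L	686
Putamen_R	R	497
Pallidum_L	L	339
Pallidum_R	R	550
Thalamus_L	L	377
Thalamus_R	R	457
Heschl_L	L	415
Heschl_R	R	327
Temporal_Sup_L	L	776
Temporal_Sup_R	R	274
Temporal_Pole_Sup_L	L	511
Temporal_Pole_Sup_R	R	563
Temporal_Mid_L	L	569
Temporal_Mid_R	R	652
Temporal_Pole_Mid_L	L	314
Temporal_Pole_Mid_R	R	840
Temporal_Inf_L	L	205
Temporal_Inf_R	R	572
Cerebelum_Crus1_L	L	1280
Cerebelum_Crus1_R	R	369
Cerebelum_Crus2_L	L	319
Cerebelum_Crus2_R	R	708
Cerebelum_3_L	L	353
Cerebelum_3_R	R	318
Cerebelum_4_5_L	L	664
Cerebelum_4_5_R	R	435
Cerebelum_6_L	L	243
Cerebelum_6_R	R	555
Cerebelum_7b_L	L	458
Cerebelum_7b_R	R	450
Cerebelum_8_L	L	468
Cerebelum_8_R	R	471
Cerebelum_9_L	L	333
Cerebelum_9_R	R	1172
Cerebelum_10_L	L	457
Cerebelum_10_R	R	770
Vermis_1_2	M	289
Vermis_3	M	245
Vermis_4_5	M	529
Vermis_6	M	895
Vermis_7	M	557
Vermis_8	M	424
Vermis_9	M	329
Vermis_10	M	511
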