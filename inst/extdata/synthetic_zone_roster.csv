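zone_id,province,arm
gombe_matadi,KONGO_CENTRAL,PRO_DS
kisantu,KONGO_CENTRAL,PRO_DS
ngidinga,KONGO_CENTRAL,PRO_DS
kc_comp_01,KONGO_CENTRAL,NON_PRO_DS
kc_comp_02,KONGO_CENTRAL,NON_PRO_DS
kc_comp_03,KONGO_CENTRAL,NON_PRO_DS
kc_comp_04,KONGO_CENTRAL,NON_PRO_DS
kc_comp_05,KONGO_CENTRAL,NON_PRO_DS
kc_comp_06,KONGO_CENTRAL,NON_PRO_DS
kc_comp_07,KONGO_CENTRAL,NON_PRO_DS
kc_comp_08,KONGO_CENTRAL,NON_PRO_DS
kc_comp_09,KONGO_CENTRAL,NON_PRO_DS
kc_comp_10,KONGO_CENTRAL,NON_PRO_DS
kc_comp_11,KONGO_CENTRAL,NON_PRO_DS
kc_comp_12,KONGO_CENTRAL,NON_PRO_DS
kc_comp_13,KONGO_CENTRAL,NON_PRO_DS
kc_comp_14,KONGO_CENTRAL,NON_PRO_DS
kc_comp_15,KONGO_CENTRAL,NON_PRO_DS
kc_comp_16,KONGO_CENTRAL,NON_PRO_DS
kc_comp_17,KONGO_CENTRAL,NON_PRO_DS
kc_comp_18,KONGO_CENTRAL,NON_PRO_DS
kc_comp_19,KONGO_CENTRAL,NON_PRO_DS
kc_comp_20,KONGO_CENTRAL,NON_PRO_DS
kc_comp_21,KONGO_CENTRAL,NON_PRO_DS
kc_comp_22,KONGO_CENTRAL,NON_PRO_DS
kc_comp_23,KONGO_CENTRAL,NON_PRO_DS
kc_comp_24,KONGO_CENTRAL,NON_PRO_DS
kc_comp_25,KONGO_CENTRAL,NON_PRO_DS
kc_comp_26,KONGO_CENTRAL,NON_PRO_DS
kc_comp_27,KONGO_CENTRAL,NON_PRO_DS
kc_comp_28,KONGO_CENTRAL,NON_PRO_DS
bunia,ITURI,PRO_DS
nyankunde,ITURI,PRO_DS
komanda,ITURI,PRO_DS
mambasa,ITURI,PRO_DS
tchomia,ITURI,PRO_DS
nizi,ITURI,PRO_DS
drodro,ITURI,PRO_DS
it_comp_01,ITURI,NON_PRO_DS
it_comp_02,ITURI,NON_PRO_DS
it_comp_03,ITURI,NON_PRO_DS
it_comp_04,ITURI,NON_PRO_DS
it_comp_05,ITURI,NON_PRO_DS
it_comp_06,ITURI,NON_PRO_DS
it_comp_07,ITURI,NON_PRO_DS
it_comp_08,ITURI,NON_PRO_DS
it_comp_09,ITURI,NON_PRO_DS
it_comp_10,ITURI,NON_PRO_DS
it_comp_11,ITURI,NON_PRO_DS
it_comp_12,ITURI,NON_PRO_DS
it_comp_13,ITURI,NON_PRO_DS
it_comp_14,ITURI,NON_PRO_DS
it_comp_15,ITURI,NON_PRO_DS
it_comp_16,ITURI,NON_PRO_DS
it_comp_17,ITURI,NON_PRO_DS
it_comp_18,ITURI,NON_PRO_DS
it_comp_19,ITURI,NON_PRO_DS
it_comp_20,ITURI,NON_PRO_DS
it_comp_21,ITURI,NON_PRO_DS
it_comp_22,ITURI,NON_PRO_DS
it_comp_23,ITURI,NON_PRO_DS
it_comp_24,ITURI,NON_PRO_DS
it_comp_25,ITURI,NON_PRO_DS
it_comp_26,ITURI,NON_PRO_DS
it_comp_27,ITURI,NON_PRO_DS
it_comp_28,ITURI,NON_PRO_DS
it_comp_29,ITURI,NON_PRO_DS
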