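category,baseline_stock_Mm3,baseline_area_Mha,legal_volume_Mm3,legal_area_Mha,legal_profit_musd,illegal_volume_Mm3,illegal_area_Mha,illegal_profit_musd
total,4835,516,1250,84.6,45116,1321,91.1,53594
national_forest,223,14.5,92.8,5.4,2859,39.5,2.2,1579
undesignated_federal,428,39.7,227,15.6,9044,295,20.2,12478
undesignated_state,586,37.5,182,9.4,6134,233,14.1,9841
private_nonprotected,792,215,412,36.1,16911,550,45.9,23314
sustainable_use_other,871,56.6,336,18.1,10168,204,8.7,6382
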