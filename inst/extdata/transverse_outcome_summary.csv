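aida_class,detailed_outcome,stratum,n
0,OPERATIVE_VD,TRANSITIONAL,1
1,ICD,TRANSITIONAL,1
1,SPONTANEOUS,TRANSITIONAL,1
2,ICD,CLASSIC,2
2,ICD,NEAR,2
2,ICD,TRANSITIONAL,2
2,ICD_AFTER_FAILURE,CLASSIC,1
2,ICD_AFTER_FAILURE,NEAR,1
2,ICD_AFTER_FAILURE,TRANSITIONAL,1
2,OPERATIVE_VD,CLASSIC,1
3,ICD,CLASSIC,12
3,ICD,NEAR,3
3,ICD,TRANSITIONAL,8
3,ICD_AFTER_FAILURE,CLASSIC,3
3,ICD_AFTER_FAILURE,TRANSITIONAL,3
3,OPERATIVE_VD,CLASSIC,1
3,OPERATIVE_VD,TRANSITIONAL,2
4,ICD,CLASSIC,7
4,ICD,NEAR,2
4,ICD,TRANSITIONAL,9
4,ICD_AFTER_FAILURE,CLASSIC,2
4,ICD_AFTER_FAILURE,NEAR,1
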