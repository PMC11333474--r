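"model_id","drug_a","drug_b","conc_a","conc_b","replicate","signal","role"
"CHP-134","isotretinoin","",0.01,0,1,9846.9,"treatment"
"CHP-134","isotretinoin","",0.01,0,2,10312.7,"treatment"
"CHP-134","isotretinoin","",0.0372759372031494,0,1,9408.2,"treatment"
"CHP-134","isotretinoin","",0.0372759372031494,0,2,9367.2,"treatment"
"CHP-134","isotretinoin","",0.138949549437314,0,1,9097.6,"treatment"
"CHP-134","isotretinoin","",0.138949549437314,0,2,8721.9,"treatment"
"CHP-134","isotretinoin","",0.517947467923121,0,1,6523.9,"treatment"
"CHP-134","isotretinoin","",0.517947467923121,0,2,6231.4,"treatment"
"CHP-134","isotretinoin","",1.93069772888325,0,1,2931.9,"treatment"
"CHP-134","isotretinoin","",1.93069772888325,0,2,3308.4,"treatment"
"CHP-134","isotretinoin","",7.19685673001151,0,1,1173.1,"treatment"
"CHP-134","isotretinoin","",7.19685673001151,0,2,1236.4,"treatment"
"CHP-134","isotretinoin","",26.8269579527972,0,1,366.6,"treatment"
"CHP-134","isotretinoin","",26.8269579527972,0,2,336.4,"treatment"
"CHP-134","isotretinoin","",100,0,1,99.2,"treatment"
"CHP-134","isotretinoin","",100,0,2,94.9,"treatment"
"CHP-134","isotretinoin","",0,0,1,10770.7,"negative_control"
"CHP-134","isotretinoin","",0,0,2,9852.9,"negative_control"
"CHP-134","isotretinoin","",0,0,3,10796.3,"negative_control"
"CHP-134","isotretinoin","",0,0,4,9869.8,"negative_control"
"CHP-134","isotretinoin","",0,0,1,0,"positive_control"
"CHP-134","isotretinoin","",0,0,2,0,"positive_control"
"CHP-134","isotretinoin","",0,0,3,0,"positive_control"
"CHP-134","isotretinoin","",0,0,4,0,"positive_control"
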