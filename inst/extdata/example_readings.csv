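subject_id,reader_id,reader_role,classification,value
p1,dev,device,Shape,oval
p1,rad1,radiologist,Shape,oval
p1,rad2,radiologist,Shape,oval
p1,rad3,radiologist,Shape,round
p2,dev,device,Shape,oval
p2,rad1,radiologist,Shape,oval
p2,rad2,radiologist,Shape,oval
p2,rad3,radiologist,Shape,oval
p3,dev,device,Shape,round
p3,rad1,radiologist,Shape,round
p3,rad2,radiologist,Shape,irregular
p3,rad3,radiologist,Shape,round
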