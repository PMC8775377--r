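kind,t0,duration,DGS,DGF,hr_pct
meal,600,,47.6,0,
meal,840,,41,0,
meal,1080,,16.3,0,
meal,1260,,16.8,22.9,
activity,510,60,,,12
activity,570,30,,,28
activity,605,85,,,35
activity,690,150,,,12
activity,870,90,,,10
activity,990,90,,,12
activity,1080,120,,,35
activity,1200,60,,,28
activity,1290,149,,,10
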