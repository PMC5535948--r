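protein,apo_mass,prep,ph,label,n_zn,n_cd,n_cu,n_s,major,exp_mm,calc_mm
BgwtMT,12652.3,Zn,7.0,Zn9,9,0,0,0,0,13221,13222.8
BgwtMT,12652.3,Zn,7.0,Zn10,10,0,0,0,1,13286,13286.2
BgwtMT,12652.3,Zn,7.0,Zn11,11,0,0,0,1,13350,13349.6
BgwtMT,12652.3,Zn,7.0,Zn12,12,0,0,0,0,13414,13413.0
BgwtMT,12652.3,Zn,2.4,apo,0,0,0,0,1,12652,12652.3
BgKNMT,12638.2,Zn,7.0,Zn9,9,0,0,0,0,13207,13208.7
BgKNMT,12638.2,Zn,7.0,Zn10,10,0,0,0,1,13272,13272.1
BgKNMT,12638.2,Zn,7.0,Zn11,11,0,0,0,1,13336,13335.5
BgKNMT,12638.2,Zn,7.0,Zn12,12,0,0,0,0,13400,13398.9
BgKNMT,12638.2,Zn,2.4,apo,0,0,0,0,1,12639,12638.2
BgwtMT,12652.3,Cd,7.0,Cd12,0,12,0,0,0,13980,13977.2
BgwtMT,12652.3,Cd,7.0,Cd13,0,13,0,0,0,14090,14087.6
BgwtMT,12652.3,Cd,7.0,Cd14S,0,14,0,1,1,14229,14230.0
BgwtMT,12652.3,Cd,7.0,Cd15S,0,15,0,1,0,14341,14340.5
BgwtMT,12652.3,Cd,7.0,Cd16,0,16,0,0,0,14418,14418.9
BgwtMT,12652.3,Cd,2.4,apo,0,0,0,0,0,12652,12652.3
BgwtMT,12652.3,Cd,2.4,Cd7S,0,7,0,1,0,13457,13457.2
BgwtMT,12652.3,Cd,2.4,Cd8S,0,8,0,1,1,13567,13567.6
BgKNMT,12638.2,Cd,7.0,Cd12,0,12,0,0,0,13960,13963.2
BgKNMT,12638.2,Cd,7.0,Cd13,0,13,0,0,0,14075,14073.6
BgKNMT,12638.2,Cd,7.0,Cd14S,0,14,0,1,1,14215,14216.0
BgKNMT,12638.2,Cd,7.0,Cd15S,0,15,0,1,0,14327,14326.4
BgKNMT,12638.2,Cd,7.0,Cd16,0,16,0,0,0,14406,14404.8
BgKNMT,12638.2,Cd,2.4,apo,0,0,0,0,1,12638,12638.2
BgKNMT,12638.2,Cd,2.4,Cd7S,0,7,0,1,0,13442,13443.1
BgKNMT,12638.2,Cd,2.4,Cd8S,0,8,0,1,1,13553,13553.5
BgwtMT,12652.3,Cu,7.0,M11,0,0,11,0,0,13341,13340.4
BgwtMT,12652.3,Cu,7.0,M12,0,0,12,0,0,13403,13402.9
BgwtMT,12652.3,Cu,7.0,M13,0,0,13,0,1,13467,13465.5
BgwtMT,12652.3,Cu,7.0,M14,0,0,14,0,1,13529,13528.0
BgwtMT,12652.3,Cu,7.0,M15,0,0,15,0,0,13588,13590.6
BgwtMT,12652.3,Cu,7.0,M16,0,0,16,0,0,13653,13653.1
BgwtMT,12652.3,Cu,2.4,Cu8,0,0,8,0,0,13153,13152.7
BgwtMT,12652.3,Cu,2.4,Cu9,0,0,9,0,0,13215,13215.3
BgwtMT,12652.3,Cu,2.4,Cu10,0,0,10,0,0,13277,13277.8
BgwtMT,12652.3,Cu,2.4,Cu11,0,0,11,0,0,13340,13340.4
BgwtMT,12652.3,Cu,2.4,Cu12,0,0,12,0,1,13403,13402.9
BgwtMT,12652.3,Cu,2.4,Cu13,0,0,13,0,0,13465,13465.5
BgwtMT,12652.3,Cu,2.4,Cu14,0,0,14,0,0,13526,13528.0
BgKNMT,12638.2,Cu,7.0,M13,0,0,13,0,0,13452,13451.4
BgKNMT,12638.2,Cu,7.0,M14,0,0,14,0,0,13514,13513.9
BgKNMT,12638.2,Cu,7.0,M15,0,0,15,0,1,13577,13576.5
BgKNMT,12638.2,Cu,7.0,M16,0,0,16,0,1,13639,13639.0
BgKNMT,12638.2,Cu,7.0,M17,0,0,17,0,0,13701,13701.6
BgKNMT,12638.2,Cu,7.0,M18,0,0,18,0,0,13762,13764.1
BgKNMT,12638.2,Cu,2.4,Cu12,0,0,12,0,0,13388,13388.8
BgKNMT,12638.2,Cu,2.4,Cu13,0,0,13,0,0,13450,13451.4
BgKNMT,12638.2,Cu,2.4,Cu14,0,0,14,0,1,13514,13513.9
BgKNMT,12638.2,Cu,2.4,Cu15,0,0,15,0,0,13575,13576.5
BgKNMT,12638.2,Cu,2.4,Cu16,0,0,16,0,0,13637,13639.0
BgKNMT,12638.2,Cu,2.4,Cu17,0,0,17,0,0,13697,13701.6
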