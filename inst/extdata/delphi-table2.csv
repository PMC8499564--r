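"item","GP1","GP2","GP3","GP4","GP5","GP6","GP7","GP8"
"Everyday Help / Everyday Companion",1,0,1,0,0,0,0,0
"Housekeeper / Home Assistant",1,0,1,0,1,0,0,0
"Occupational Therapy",1,1,1,0,1,0,1,1
"Check of prescription drugs",1,0,0,0,0,0,0,0
"Nursing Service (mainly preparing medication)",1,1,1,0,1,0,1,0
"Pill Box",1,0,0,0,0,0,0,0
"Walker / Walker Training",1,0,1,0,1,0,1,1
"Sports Group",0,0,1,0,1,0,0,0
"Physiotherapy / Remedial Gymnastics",1,1,0,0,0,0,1,0
"Personal Emergency Response System",0,0,1,1,1,0,1,0
"Audiologist",0,0,0,0,0,0,0,1
"Assistive products for personal hygiene",1,1,0,0,0,0,0,0
"Mobile-Care Services (1-2 times weekly)",0,0,1,1,0,0,0,0
"Meals on Wheels",0,0,0,0,1,0,0,0
"Mapping of available Support-network",0,0,0,0,0,1,0,0
"Local non-profit support services",0,0,0,0,0,0,1,1
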