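"item","GP1","GP2","GP3","GP4","GP5","GP6","GP7","GP8"
"Housekeeper / Home Assistant",1,1,1,1,1,1,1,0
"Everyday Help / Everyday Companion",1,1,1,0,1,0,1,0
"Occupational Therapy / Memory Training",1,1,1,0,1,1,1,0
"Check of prescription drugs",1,0,1,0,1,0,0,1
"Nursing Service (mainly preparing medication)",1,1,1,0,1,0,0,0
"Discuss medication regime with life partner",1,0,1,0,0,0,0,0
"Pick-up and Return Services",1,0,0,0,0,0,0,0
"Sports Group",1,0,1,0,1,0,0,0
"Physiotherapy / Gait Training",1,0,1,0,1,0,0,0
"Personal Emergency Response System",0,0,0,1,1,1,0,0
"Respiration Therapy",0,0,0,0,0,0,1,0
"Support Services (public transportation)",0,0,0,0,0,0,0,1
"Local guidance office for the elderly",1,0,0,0,0,0,0,0
"Psychosocial Counselling",0,1,0,0,0,0,0,0
"Nutritional plan and counselling",0,0,1,0,0,0,0,0
"Assistive Products for Personal Hygiene",0,0,0,1,1,0,0,0
"Self-help Group",0,0,0,0,0,1,0,0
"Sociotherapy",0,0,0,0,0,0,1,0
"Walker / Walker Training",0,0,0,0,0,0,0,1
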