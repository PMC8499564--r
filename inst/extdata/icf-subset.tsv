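# ICF taxonomy subset (code<TAB>title), WHO ICF category titles.
# Covers the codes used by the bundled mapping rules, case-vignette
# profiles and demonstration service catalogue, closed under parents.
# A full classification file in the same format can be supplied instead.
b1	Mental functions
b114	Orientation functions
b130	Energy and drive functions
b134	Sleep functions
b140	Attention functions
b144	Memory functions
b152	Emotional functions
b2	Sensory functions and pain
b210	Seeing functions
b230	Hearing functions
b280	Sensation of pain
b4	Functions of the cardiovascular, haematological, immunological and respiratory systems
b440	Respiration functions
b455	Exercise tolerance functions
b5	Functions of the digestive, metabolic and endocrine systems
b530	Weight maintenance functions
b7	Neuromusculoskeletal and movement-related functions
b710	Mobility of joint functions
b730	Muscle power functions
b770	Gait pattern functions
d2	General tasks and demands
d230	Carrying out daily routine
d240	Handling stress and other psychological demands
d3	Communication
d310	Communicating with - receiving - spoken messages
d4	Mobility
d410	Changing basic body position
d415	Maintaining a body position
d450	Walking
d4500	Walking short distances
d4501	Walking long distances
d455	Moving around
d460	Moving around in different locations
d465	Moving around using equipment
d470	Using transportation
d475	Driving
d5	Self-care
d510	Washing oneself
d520	Caring for body parts
d540	Dressing
d550	Eating
d570	Looking after one's health
d5700	Ensuring one's physical comfort
d5701	Managing diet and fitness
d5702	Maintaining one's health
d6	Domestic life
d620	Acquisition of goods and services
d630	Preparing meals
d640	Doing housework
d6400	Washing and drying clothes
d660	Assisting others
d8	Major life areas
d860	Basic economic transactions
d9	Community, social and civic life
d910	Community life
d920	Recreation and leisure
e1	Products and technology
e110	Products or substances for personal consumption
e115	Products and technology for personal use in daily living
e120	Products and technology for personal indoor and outdoor mobility and transportation
e3	Support and relationships
e310	Immediate family
e320	Friends
e5	Services, systems and policies
e575	General social support services, systems and policies
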