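{
  "name": "icfmatch demonstration catalogue",
  "version": "1.0",
  "services": [
    {
      "id": "audiologist",
      "name": "Audiologist",
      "category": "medical",
      "targets": ["b230"],
      "description": "Hearing assessment and hearing-aid fitting."
    },
    {
      "id": "elderly_guidance_office",
      "name": "Local guidance office for the elderly",
      "category": "social_care",
      "targets": ["d570", "d620"],
      "description": "Advice on care options and entitlements."
    },
    {
      "id": "emergency_response_system",
      "name": "Personal Emergency Response System",
      "category": "assistive_product",
      "targets": ["d240"],
      "description": "Wearable alarm to summon help at home; addresses coping with safety-critical situations."
    },
    {
      "id": "everyday_companion",
      "name": "Everyday Help / Everyday Companion",
      "category": "social_care",
      "targets": ["d460", "d620"],
      "description": "Accompaniment for errands and getting around the neighbourhood."
    },
    {
      "id": "housekeeper",
      "name": "Housekeeper / Home Assistant",
      "category": "social_care",
      "targets": ["d620", "d640"],
      "description": "Help with housework and acquiring goods of daily living."
    },
    {
      "id": "hygiene_products",
      "name": "Assistive Products for Personal Hygiene",
      "category": "assistive_product",
      "targets": ["d510", "d520"],
      "description": "Shower chairs, grab rails and related washing aids."
    },
    {
      "id": "meals_on_wheels",
      "name": "Meals on Wheels",
      "category": "social_care",
      "targets": ["d550", "d630"],
      "description": "Delivered warm meals replacing meal preparation."
    },
    {
      "id": "medication_partner_counselling",
      "name": "Discuss medication regime with life partner",
      "category": "social_care",
      "targets": ["d5702", "e310"],
      "description": "Involving the partner in managing the medication plan."
    },
    {
      "id": "medication_review",
      "name": "Check of prescription drugs",
      "category": "medical",
      "targets": ["d5702"],
      "description": "Structured review of the prescription list (polypharmacy check)."
    },
    {
      "id": "mobile_care",
      "name": "Mobile-Care Services (1-2 times weekly)",
      "category": "social_care",
      "targets": ["d510", "d520", "d540"],
      "description": "Visiting care workers supporting washing and dressing."
    },
    {
      "id": "nonprofit_support",
      "name": "Local non-profit support services",
      "category": "social_care",
      "targets": ["d620", "d640", "e575"],
      "description": "Volunteer-based household and errand support."
    },
    {
      "id": "nursing_service",
      "name": "Nursing Service (mainly preparing medication)",
      "category": "social_care",
      "targets": ["d570", "d5702"],
      "description": "Ambulant nursing, chiefly preparing and supervising medication."
    },
    {
      "id": "nutrition_counselling",
      "name": "Nutritional plan and counselling",
      "category": "medical",
      "targets": ["b530", "d5701", "d630"],
      "description": "Dietary planning and weight management advice."
    },
    {
      "id": "occupational_therapy",
      "name": "Occupational Therapy / Memory Training",
      "category": "medical",
      "targets": ["b144", "d640"],
      "description": "Restoring everyday competence; includes cognitive training."
    },
    {
      "id": "physiotherapy",
      "name": "Physiotherapy / Gait Training / Remedial Gymnastics",
      "category": "medical",
      "targets": ["b710", "b770", "d450"],
      "description": "Exercise therapy for gait, joint mobility and strength."
    },
    {
      "id": "pickup_return_service",
      "name": "Pick-up and Return Services",
      "category": "social_care",
      "targets": ["d460", "d470"],
      "description": "Door-to-door transport to appointments."
    },
    {
      "id": "pill_box",
      "name": "Pill Box",
      "category": "assistive_product",
      "targets": ["d5702"],
      "description": "Weekly dispenser supporting correct medication intake."
    },
    {
      "id": "psychosocial_counselling",
      "name": "Psychosocial Counselling",
      "category": "medical",
      "targets": ["b152"],
      "description": "Counselling for mood problems and emotional strain."
    },
    {
      "id": "respiration_therapy",
      "name": "Respiration Therapy",
      "category": "medical",
      "targets": ["b440"],
      "description": "Breathing exercises for chronic pulmonary conditions."
    },
    {
      "id": "self_help_group",
      "name": "Self-help Group",
      "category": "social_care",
      "targets": ["b152", "d920"],
      "description": "Peer group for emotional support and shared activity."
    },
    {
      "id": "sociotherapy",
      "name": "Sociotherapy",
      "category": "medical",
      "targets": ["b152", "d240", "d910"],
      "description": "Guided re-engagement with community life for psychic strain."
    },
    {
      "id": "sports_group",
      "name": "Sports Group",
      "category": "social_care",
      "targets": ["b455", "d450", "d920"],
      "description": "Group exercise for endurance and mobility."
    },
    {
      "id": "support_network_mapping",
      "name": "Mapping of available Support-network",
      "category": "social_care",
      "targets": ["e310", "e320"],
      "description": "Charting which family and friends can take on support tasks."
    },
    {
      "id": "transport_support",
      "name": "Support Services (public transportation)",
      "category": "social_care",
      "targets": ["d470"],
      "description": "Assistance using public transportation."
    },
    {
      "id": "walking_frame",
      "name": "Walker / Walker Training",
      "category": "assistive_product",
      "targets": ["d450", "d465"],
      "description": "Walking frame provision and training in its use."
    }
  ]
}
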