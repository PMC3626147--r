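{
  "scales": [
    {
      "factor": "salience_coherence",
      "reported_alpha": 0.73,
      "items": [
        {"item_id": "sal_1", "text": "Colorectal cancer screening makes sense to me.", "reverse_coded": false, "tailoring": false},
        {"item_id": "sal_2", "text": "Having colorectal cancer screening is an important thing for me to do.", "reverse_coded": false, "tailoring": true},
        {"item_id": "sal_3", "text": "Having colorectal cancer screening can help to protect my health.", "reverse_coded": false, "tailoring": false},
        {"item_id": "sal_4", "text": "I will be just as healthy if I avoid having colorectal cancer screening.", "reverse_coded": true, "tailoring": false}
      ]
    },
    {
      "factor": "social_influence",
      "reported_alpha": 0.62,
      "items": [
        {"item_id": "soc_1", "text": "I want to do what members of my immediate family think I should do about colorectal cancer screening.", "reverse_coded": false, "tailoring": false},
        {"item_id": "soc_2", "text": "Members of my immediate family think I should have colorectal cancer screening.", "reverse_coded": false, "tailoring": true},
        {"item_id": "soc_3", "text": "My doctor or health professional thinks I should have colorectal cancer screening.", "reverse_coded": false, "tailoring": false, "note": "also flagged as a tailoring statement in the source instrument; the registry designates exactly one tailoring item per factor and uses the first flagged item (soc_2)"},
        {"item_id": "soc_4", "text": "I want to do what my doctor or health professional thinks I should do about colorectal cancer screening.", "reverse_coded": false, "tailoring": false}
      ]
    },
    {
      "factor": "cancer_worries",
      "reported_alpha": 0.80,
      "items": [
        {"item_id": "wor_1", "text": "I am afraid of having an abnormal colorectal cancer screening test result.", "reverse_coded": false, "tailoring": false},
        {"item_id": "wor_2", "text": "I am worried that colorectal cancer screening will show that I have colorectal cancer or polyps.", "reverse_coded": false, "tailoring": false}
      ]
    },
    {
      "factor": "perceived_susceptibility",
      "reported_alpha": 0.65,
      "items": [
        {"item_id": "sus_1", "text": "The chance that I might develop colorectal cancer is high.", "reverse_coded": false, "tailoring": false},
        {"item_id": "sus_2", "text": "Compared with other persons my age, I am at lower risk for colorectal cancer.", "reverse_coded": true, "tailoring": false},
        {"item_id": "sus_3", "text": "It is very likely that I will develop colorectal cancer or polyps.", "reverse_coded": false, "tailoring": false},
        {"item_id": "sus_4", "text": "The chances that I will develop colorectal polyps are high.", "reverse_coded": false, "tailoring": true}
      ]
    },
    {
      "factor": "response_efficacy",
      "reported_alpha": 0.59,
      "items": [
        {"item_id": "eff_1", "text": "When colorectal polyps are found and removed, colorectal cancer can be prevented.", "reverse_coded": false, "tailoring": true},
        {"item_id": "eff_2", "text": "When colorectal cancer is found early, it can be cured.", "reverse_coded": false, "tailoring": false}
      ]
    },
    {
      "factor": "self_efficacy",
      "reported_alpha": 0.75,
      "items": [
        {"item_id": "se_1", "text": "I think that doing the test would be easy for me.", "reverse_coded": false, "tailoring": true},
        {"item_id": "se_2", "text": "Finding time to do the test would be difficult for me.", "reverse_coded": true, "tailoring": false},
        {"item_id": "se_3", "text": "Completing the test correctly would be easy for me.", "reverse_coded": false, "tailoring": false}
      ]
    },
    {
      "factor": "fecal_aversion",
      "reported_alpha": 0.71,
      "items": [
        {"item_id": "fa_1", "text": "Collecting feces for the purpose of bowel cancer screening is unhygienic.", "reverse_coded": true, "tailoring": false},
        {"item_id": "fa_2", "text": "Collecting feces for the purpose of bowel cancer screening is distasteful.", "reverse_coded": true, "tailoring": true},
        {"item_id": "fa_3", "text": "Giving a sample of feces to another person is embarrassing.", "reverse_coded": true, "tailoring": false}
      ]
    }
  ]
}
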