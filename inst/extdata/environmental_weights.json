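[
  {"factor_id": "sex", "level": "F", "odds_ratio": 2.22, "ci": null, "category": "environmental", "source_note": "female vs male, meta-analysis"},
  {"factor_id": "birth_month", "level": "4", "odds_ratio": 1.08, "ci": null, "category": "environmental", "source_note": "April birth"},
  {"factor_id": "birth_month", "level": "5", "odds_ratio": 1.09, "ci": null, "category": "environmental", "source_note": "May birth"},
  {"factor_id": "birth_month", "level": "10", "odds_ratio": 0.95, "ci": null, "category": "environmental", "source_note": "October birth"},
  {"factor_id": "birth_month", "level": "11", "odds_ratio": 0.90, "ci": null, "category": "environmental", "source_note": "November birth"},
  {"factor_id": "im_history", "level": "yes", "odds_ratio": 2.17, "ci": null, "category": "environmental", "source_note": "previous infectious mononucleosis"},
  {"factor_id": "ebna1", "level": "undetectable", "odds_ratio": 0.33, "ci": null, "category": "environmental", "source_note": "anti-EBNA-1 IgG undetectable"},
  {"factor_id": "ebna1", "level": "Q1", "odds_ratio": 1.0, "ci": null, "category": "environmental", "source_note": "anti-EBNA-1 IgG lowest quintile (reference)"},
  {"factor_id": "ebna1", "level": "Q2", "odds_ratio": 2.6, "ci": [0.7, 9.2], "category": "environmental", "source_note": "anti-EBNA-1 IgG quintile 2"},
  {"factor_id": "ebna1", "level": "Q3", "odds_ratio": 3.2, "ci": [1.0, 10.4], "category": "environmental", "source_note": "anti-EBNA-1 IgG quintile 3"},
  {"factor_id": "ebna1", "level": "Q4", "odds_ratio": 5.1, "ci": [1.5, 17.6], "category": "environmental", "source_note": "anti-EBNA-1 IgG quintile 4"},
  {"factor_id": "ebna1", "level": "Q5", "odds_ratio": 9.4, "ci": [2.5, 35.4], "category": "environmental", "source_note": "anti-EBNA-1 IgG highest quintile"},
  {"factor_id": "vitd", "level": "Q1", "odds_ratio": 1.0, "ci": null, "category": "vitamin_d", "source_note": "25-OHvD lowest quintile, <63.2 nmol/l (reference)"},
  {"factor_id": "vitd", "level": "Q2", "odds_ratio": 0.57, "ci": [0.3, 1.07], "category": "vitamin_d", "source_note": "25-OHvD 63.3-75.3 nmol/l"},
  {"factor_id": "vitd", "level": "Q3", "odds_ratio": 0.57, "ci": [0.3, 1.07], "category": "vitamin_d", "source_note": "25-OHvD 75.4-84.8 nmol/l"},
  {"factor_id": "vitd", "level": "Q4", "odds_ratio": 0.74, "ci": [0.4, 1.36], "category": "vitamin_d", "source_note": "25-OHvD 84.9-99.1 nmol/l"},
  {"factor_id": "vitd", "level": "Q5", "odds_ratio": 0.38, "ci": [0.19, 0.75], "category": "vitamin_d", "source_note": "25-OHvD highest quintile, >99.2 nmol/l"},
  {"factor_id": "smoking", "level": "ever", "odds_ratio": 1.52, "ci": null, "category": "environmental", "source_note": "ever smoking (self-report or cotinine > 3.08 ng/ml)"},
  {"factor_id": "hla_drb1_1501", "level": "heterozygote", "odds_ratio": 3.1, "ci": null, "category": "hla", "source_note": "HLA-DRB1*1501 heterozygote"},
  {"factor_id": "hla_drb1_1501", "level": "homozygote", "odds_ratio": 6.2, "ci": null, "category": "hla", "source_note": "HLA-DRB1*1501 homozygote"}
]
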