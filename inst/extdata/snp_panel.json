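[
  {"snp_id": "rs1315388", "gene": "HLA-DRB1*1501", "risk_allele": "A", "odds_ratio": 3.10},
  {"snp_id": "rs4648356", "gene": "MMEL1", "risk_allele": "C", "odds_ratio": 1.14},
  {"snp_id": "rs11810217", "gene": "EV15", "risk_allele": "A", "odds_ratio": 1.15},
  {"snp_id": "rs11581062", "gene": "VCAM1", "risk_allele": "G", "odds_ratio": 1.12},
  {"snp_id": "rs1335532", "gene": "CD58", "risk_allele": "A", "odds_ratio": 1.22},
  {"snp_id": "rs1323292", "gene": "RGS1", "risk_allele": "A", "odds_ratio": 1.12},
  {"snp_id": "rs7522462", "gene": "C1orf106(KIF21B)", "risk_allele": "G", "odds_ratio": 1.11},
  {"snp_id": "rs12466022", "gene": "no gene", "risk_allele": "C", "odds_ratio": 1.11},
  {"snp_id": "rs7595037", "gene": "PLEK", "risk_allele": "A", "odds_ratio": 1.11},
  {"snp_id": "rs17174870", "gene": "MERTK", "risk_allele": "G", "odds_ratio": 1.11},
  {"snp_id": "rs10201872", "gene": "SP140", "risk_allele": "A", "odds_ratio": 1.14},
  {"snp_id": "rs11129295", "gene": "EOMES", "risk_allele": "A", "odds_ratio": 1.11},
  {"snp_id": "rs669607", "gene": "no gene", "risk_allele": "C", "odds_ratio": 1.13},
  {"snp_id": "rs2028597", "gene": "CBLB", "risk_allele": "G", "odds_ratio": 1.13},
  {"snp_id": "rs2293370", "gene": "TMEM39A/CD80", "risk_allele": "G", "odds_ratio": 1.13},
  {"snp_id": "rs9282641", "gene": "CD86", "risk_allele": "G", "odds_ratio": 1.21},
  {"snp_id": "rs2243123", "gene": "IL12A", "risk_allele": "G", "odds_ratio": 1.08},
  {"snp_id": "rs228614", "gene": "NFKB1", "risk_allele": "G", "odds_ratio": 1.09},
  {"snp_id": "rs6897932", "gene": "IL7R", "risk_allele": "G", "odds_ratio": 1.11},
  {"snp_id": "rs4613763", "gene": "PTGER4", "risk_allele": "G", "odds_ratio": 1.20},
  {"snp_id": "rs2546890", "gene": "IL12B", "risk_allele": "A", "odds_ratio": 1.11},
  {"snp_id": "rs12212193", "gene": "BACH2", "risk_allele": "G", "odds_ratio": 1.09},
  {"snp_id": "rs802734", "gene": "THEMIS", "risk_allele": "A", "odds_ratio": 1.10},
  {"snp_id": "rs11154801", "gene": "MYB/AHI1", "risk_allele": "A", "odds_ratio": 1.13},
  {"snp_id": "rs17066096", "gene": "IL22RA2", "risk_allele": "G", "odds_ratio": 1.14},
  {"snp_id": "rs13192841", "gene": "no gene", "risk_allele": "A", "odds_ratio": 1.10},
  {"snp_id": "rs1738074", "gene": "TAGAP", "risk_allele": "G", "odds_ratio": 1.13},
  {"snp_id": "rs354033", "gene": "ZNF746", "risk_allele": "G", "odds_ratio": 1.11},
  {"snp_id": "rs1520333", "gene": "IL7", "risk_allele": "G", "odds_ratio": 1.10},
  {"snp_id": "rs4410871", "gene": "MYC", "risk_allele": "G", "odds_ratio": 1.11},
  {"snp_id": "rs2019960", "gene": "PVT1", "risk_allele": "G", "odds_ratio": 1.12},
  {"snp_id": "rs3118470", "gene": "IL2RA", "risk_allele": "G", "odds_ratio": 1.12},
  {"snp_id": "rs1250550", "gene": "ZMIZ1", "risk_allele": "A", "odds_ratio": 1.10},
  {"snp_id": "rs7923837", "gene": "HHEX", "risk_allele": "G", "odds_ratio": 1.10},
  {"snp_id": "rs650258", "gene": "CD6", "risk_allele": "G", "odds_ratio": 1.12},
  {"snp_id": "rs630923", "gene": "CXCR5", "risk_allele": "C", "odds_ratio": 1.12},
  {"snp_id": "rs1800693", "gene": "TNFRSF1A", "risk_allele": "G", "odds_ratio": 1.12},
  {"snp_id": "rs10466829", "gene": "CLEC1", "risk_allele": "A", "odds_ratio": 1.09},
  {"snp_id": "rs12368653", "gene": "CYP27B1", "risk_allele": "A", "odds_ratio": 1.10},
  {"snp_id": "rs949143", "gene": "ARL6IP4", "risk_allele": "G", "odds_ratio": 1.08},
  {"snp_id": "rs4902647", "gene": "ZFP36L1", "risk_allele": "G", "odds_ratio": 1.11},
  {"snp_id": "rs2300603", "gene": "BATF", "risk_allele": "A", "odds_ratio": 1.11},
  {"snp_id": "rs2119704", "gene": "GALC/GPR65", "risk_allele": "C", "odds_ratio": 1.22},
  {"snp_id": "rs2744148", "gene": "SOX8", "risk_allele": "G", "odds_ratio": 1.12},
  {"snp_id": "rs7200786", "gene": "CLEC16A", "risk_allele": "A", "odds_ratio": 1.15},
  {"snp_id": "rs13333054", "gene": "IRF8", "risk_allele": "A", "odds_ratio": 1.11},
  {"snp_id": "rs9891119", "gene": "STAT3", "risk_allele": "C", "odds_ratio": 1.11},
  {"snp_id": "rs180515", "gene": "RPS6KB1", "risk_allele": "G", "odds_ratio": 1.09},
  {"snp_id": "rs7238078", "gene": "MALT1", "risk_allele": "A", "odds_ratio": 1.12},
  {"snp_id": "rs1077667", "gene": "TNFRSF14", "risk_allele": "G", "odds_ratio": 1.16},
  {"snp_id": "rs8112449", "gene": "TYK2/CDC37", "risk_allele": "G", "odds_ratio": 1.08},
  {"snp_id": "rs874628", "gene": "MPV17L2", "risk_allele": "A", "odds_ratio": 1.11},
  {"snp_id": "rs2303759", "gene": "DKKL1", "risk_allele": "C", "odds_ratio": 1.11},
  {"snp_id": "rs2425752", "gene": "CD40", "risk_allele": "A", "odds_ratio": 1.11},
  {"snp_id": "rs2248359", "gene": "CYP24A1", "risk_allele": "G", "odds_ratio": 1.12},
  {"snp_id": "rs6062314", "gene": "ZBTB46/TNFRSF6B", "risk_allele": "A", "odds_ratio": 1.16},
  {"snp_id": "rs2283792", "gene": "MAPK1", "risk_allele": "C", "odds_ratio": 1.10},
  {"snp_id": "rs140522", "gene": "SCO2", "risk_allele": "A", "odds_ratio": 1.10}
]
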