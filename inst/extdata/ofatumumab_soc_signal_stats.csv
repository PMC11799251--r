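soc,a,ror,ror_lo95,ror_hi95,prr,chi2,ebgm,ebgm05,ic,ic025,flagged
Infections and infestations,4597,0.73,0.71,0.76,0.75,376.81,0.77,0.75,-0.37,-0.42,FALSE
Blood and lymphatic system disorders,223,0.39,0.34,0.44,0.39,207.24,0.41,0.37,-1.27,-1.47,FALSE
Investigations,1735,0.42,0.40,0.45,0.44,1252.73,0.47,0.45,-1.10,-1.17,FALSE
Immune system disorders,383,0.55,0.50,0.61,0.56,128.61,0.58,0.53,-0.78,-0.93,FALSE
Skin and subcutaneous tissue disorders,1943,0.81,0.78,0.85,0.82,72.28,0.84,0.80,-0.26,-0.33,FALSE
"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",226,0.22,0.19,0.25,0.22,621.22,0.24,0.21,-2.07,-2.26,FALSE
Reproductive system and breast disorders,213,0.65,0.57,0.75,0.66,36.10,0.68,0.60,-0.56,-0.76,FALSE
General disorders and administration site conditions,20754,2.57,2.53,2.62,2.05,11036.62,1.85,1.82,0.89,0.87,TRUE
Cardiac disorders,303,0.38,0.34,0.42,0.38,295.23,0.41,0.37,-1.30,-1.47,FALSE
Nervous system disorders,11638,0.99,0.97,1.01,0.99,1.76,0.99,0.97,-0.02,-0.04,FALSE
"Respiratory, thoracic and mediastinal disorders",2569,1.28,1.22,1.33,1.26,127.84,1.23,1.19,0.30,0.24,TRUE
Hepatobiliary disorders,100,0.30,0.25,0.37,0.31,153.59,0.33,0.28,-1.60,-1.90,FALSE
Gastrointestinal disorders,3201,0.75,0.72,0.78,0.76,228.27,0.78,0.76,-0.35,-0.41,FALSE
Musculoskeletal and connective tissue disorders,4940,1.30,1.26,1.34,1.28,274.01,1.24,1.21,0.31,0.27,TRUE
"Injury, poisoning and procedural complications",4123,0.75,0.73,0.78,0.77,290.28,0.79,0.77,-0.35,-0.39,FALSE
Metabolism and nutrition disorders,362,0.50,0.45,0.55,0.50,173.18,0.53,0.48,-0.92,-1.08,FALSE
Eye disorders,1055,0.72,0.68,0.77,0.73,101.37,0.75,0.71,-0.42,-0.51,FALSE
Psychiatric disorders,2104,0.74,0.70,0.77,0.75,176.49,0.77,0.74,-0.39,-0.45,FALSE
Ear and labyrinth disorders,350,0.90,0.81,1.01,0.90,3.27,0.91,0.83,-0.13,-0.29,FALSE
Product issues,999,4.57,4.23,4.94,4.51,1805.50,3.31,3.10,1.73,1.62,TRUE
Vascular disorders,492,0.30,0.28,0.33,0.31,747.52,0.33,0.31,-1.58,-1.72,FALSE
Social circumstances,23,0.11,0.07,0.17,0.11,161.71,0.12,0.09,-3.03,-3.62,FALSE
Renal and urinary disorders,492,0.47,0.43,0.52,0.48,269.47,0.51,0.47,-0.98,-1.12,FALSE
Endocrine disorders,49,0.34,0.26,0.45,0.34,59.69,0.37,0.29,-1.44,-1.86,FALSE
"Pregnancy, puerperium and perinatal conditions",77,0.22,0.18,0.28,0.22,206.54,0.24,0.20,-2.05,-2.38,FALSE
Surgical and medical procedures,61,0.12,0.09,0.16,0.12,385.44,0.13,0.11,-2.91,-3.27,FALSE
NANA,4,0.08,0.03,0.22,0.08,40.46,0.09,0.04,-3.46,-4.75,FALSE
"Congenital, familial and genetic disorders",10,0.17,0.09,0.32,0.17,40.05,0.19,0.11,-2.43,-3.31,FALSE
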