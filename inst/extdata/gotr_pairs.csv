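row_id,generic_name,local_proprietary,overseas_similar,overseas_generic,match_percent,risk
1,"ACA","AXAR®","RAXAR","grepafloxacin",,High
2,"ACETAMINOPHEN","TINYPHEN®","SINIPHEN","Caffeine, Propyphenazone, Salicylamide",70,High
3,"ACETAMINOPHEN/CAFFEINE/IBUPROFEN","RAHAFEN®","RAPIFEN","Alfentanil",78,High
4,"ADULT COLD PREPARATION-5","FARALEX®","FARMALEX","Cefalexin",91,High
5,"ADULT COLD PREPARATION-7","ZOCAMAX®","TOPAMAX","topiramate",67,High
6,"ADULT COLD PREPARATION-4","EXACOLD®","DEXACOL","Dexamethasone",67,High
7,"ADULT COLD","GRIPHEN®","PRIPHEN","Nandrolone",78,High
8,"AMANTADINE HCL","AMMOREL®","AMIOREL","Bromhexine",89,High
9,"AMLODIPINE/ATORVASTATIN","TENSOLIP®","TENSOLIV","chlordiazepoxide-clidinium",80,High
10,"ARIPIPRAZOLE","SEROZOL®","SEROZIL","Cefprozil",89,High
11,"ATORVASTATIN","ATOSTROL®","HALOSTROL","halobetasol propionate",80,High
12,"AZATHIOPRINE","AZARAM®","AZACTAM","aztreonam",81,High
13,"BECLOMETHASONE DIPROPIONATE","BECLORHIN®","BECLOTRIN","Betametasona +Clotrimazol+ Gentamicina",88,High
14,"BUSERELIN ACETATE","CINNAFACT®","CINNAPAC","Cinnarizine",73,High
15,"CALAMINE","CALAMEX®","CALMEX","Doxylamine",80,High
16,"CALCIUM FOLINATE","ROFOLIN®","ROFOXIN","Ceftriaxone: (ceftriaxone sodium and dextrose",89,High
17,"CEFIXIME","LOPRAX®","LOPROX","Ciclopirox",88,High
18,"CEFTIZOXIME SODIUM","AFAZOX®","AFAZOL","naphazoline hydrochloride",75,High
19,"CETIRIZINE 2HCl","CETRIKIM®","CETROTIDE","Cetrorelix",60,Medium
20,"CETIRIZINE/PSEUDOEPHEDRINE","CETADIN®","CEFADIN","Cephalexin",89,High
21,"CIPROFLOXACIN HCL","CIPLEX®","IPLEX","mecasermin rinfabate",75,High
22,"CITALOPRAM HBR","BIOXAL®","BIOXTRA","saliva substitutes topical",66,High
23,"CLOBUTINOL HCL","TIDOCAUGH®","ETIDOCAINE","Etidocaine",55,Medium
24,"CLOPIDOGREL","DIPIX®","DEPIXOL","Flupentixol",71,High
25,"CO TRIMOXAZOLE","DUCOTRI®","DUCORT","Deflazacort",72,High
26,"COLCHICINE","MODACINE®","MODACIN","Ceftazidime pentahydrate",80,High
27,"CONTRACEPTIVE HD","OVUSTOP-H®","ACUSTOP","Flurbiprofen",45,Medium
28,"DEFERASIROX","OSVERAL®","FEVERALL","Acetaminophen",67,High
29,"DIAZEPAM","ZEPADIC®","ZEPATIER","elbasvir and grazoprevir",67,High
30,"DICLOFENAC SODIUM","DICLEN®","DICLEGIS","doxylamine and pyridoxine",75,High
31,"DIMETHICONE","DILICE®","DILOMINE","dicyclomine",69,High
32,"DOMPERIDONE MALEATE","MOTIDON®","METADON","methadone",78,High
33,"ESOMEPRAZOLE","MAXOPRAZOL®","MEDOPRAZOLE","Omeprazole",75,High
34,"EXPECTORANT","COUFEX®","KEFLEX","Cephalexin",47,Medium
35,"EZETIMIBE","EZITAL®","EMITAL","Ondansetron",88,High
36,"FEXOFENADINE","ALLEXAFEN®","ALEXAN","Cytarabine",61,Medium
37,"FURAZOLIDONE","FURABEN®","FURACIN","nitrofurazone",78,High
38,"GALANTAMINE","ALZAMIN®","ALAMIN","PHENYLEPHRINE HCL/CHLORPHENIRAMINE MALEATE",83,High
39,"GEMCITABINE (as HCL)","CHEMOGEM®","CHEMOFER","Folic Acid, Iron, Vitamin B12",70,High
40,"GLATIRAMER ACETATE","OSVIMER®","OSIMERTINIB","osimertinib",78,High
41,"GRANISETRON","GRATRIL®","GABITRIL","tiagabine HCl",78,High
42,"HEPARIN SODIUM","CLOTIN®","CLOPINE","clozapine",75,High
43,"HYDROXYPROGESTERONE CAPROATE","FEMOLIFE®","MEMOLIFE","Vitamins and minerals",80,High
44,"IBUPROFEN","ACTOPIN®","ACTAPIN","Amlodipine",89,High
45,"IMIPENEM+CILASTATIN","CILAVIL®","CILARIL","Cilazapril",89,High
46,"INTERFERON ALFA-2B","PDFERON®","MYFERON","polysaccharide-iron",67,High
47,"IOHEXOL","OPAQUESOL®","ELDOPAQUE","Hidroquinone",55,Medium
48,"ISOXSUPRINE HCL","ISUPRINE®","ISUDRINE","aluminum phosphate & magnesium oxide",90,High
49,"LATANOPROST+TIMOLOL","COPROST®","CARBOPROST","carboprost",90,High
50,"LETROZOLE","LETRAX®","LETROX","levothyroxine",88,High
51,"LEVOFLOXACIN","TAVANEX®","TAVINEX","Ambroxol",89,High
52,"LIDOCAINE","XYLEX®","XYLAREX","d-xylitol",79,High
53,"LISINOPRIL","LISIREX®","LIPIREX","Atorvastatin",89,High
54,"LOSARTAN POTASSIUM","CARDIOSAN®","CARDIOGEN","cardiogen",82,High
55,"LOSARTAN/HYDROCHLOROTHIAZIDE","HYDROZAAR®","HYDROPANE","homatropine/hydrocodone",64,Medium
56,"MEBEVERINE","COLIBSAN®","COLISTIN","colistimethate sodium",77,High
57,"MEDROXYPROGESTERONE ACETATE","DEPOGESTRONE®","DEPO-TESTOSTERONE","testosterone cypionate",70,High
58,"MEDROXYPROGESTERONE ACETATE","PROVEDIC®","PROVENTIL","albuterol sulfate",67,High
59,"MELOXICAM","ROMATOBIC®","CROMATONBIC","Calcium Folinate, Vitamin B12",83,High
60,"METFORMIN HCL","METOVER®","MEROVER","meropenem",89,High
61,"METHOCARBAMOL","RELAXIMOL®","RELAXOL","Citalopram",69,High
62,"METOCLOPRAMIDE","PLADIC®","PLACIDYL","Ethchlorvynol",69,High
63,"METOPROLOL TARTRATE","TEDAPROL®","TEDAROL","Triamcinolone Diacetate",82,High
64,"MUPIROCIN","AFIROCIN®","AZITROCIN","azithromycin",85,High
65,"NANDROLONE DECANOATE","DECANDROLONE®","OXANDROLONE","Oxandrolone",71,High
66,"NAPHAZOLINE ANTAZOLINE","ANAPRIVIN®","ANAPRILIN","propranolol",91,High
67,"NAPROXEN","NAPTIN®","NAFTIN","naftifine hydrochloride",88,High
68,"NITROGLYCERIN SR","TRICONTIN®","TRICON","Fluconazole",73,High
69,"OLANZAPINE","ZYPROBIOX®","PROBIOX","Ciprofloxacin",73,High
70,"ORLISTAT","XENOLIP®","FENOLIP","fenofibrate",78,High
71,"OXYTOCIN","OXYTIP®","OXYVIT","Retinol",66,High
72,"PANTOPRAZOLE","PENTOMID®","PENTOXIL","pentoxifylline",70,High
73,"PANTOPRAZOLE","PANTOSS®","PANTOSSE","Ethylmorphine",89,High
74,"PENTOXIFYLLINE","PENTAFIL®","PENTACEL","pentacel",80,High
75,"PHENYLEPHRINE","NEOPHRIN®","NEOPYRIN","Acetaminophen",90,High
76,"POLYETHYLENGLYCOL","COLOLAX®","CODOLAX","chlorpheniramine maleate/codeine phosphate/papaverine hydrochloride",89,High
77,"PRASUGREL","BIOSUGREL®","BIOSURE","Amikacin",68,High
78,"PROPYLTHIOURACIL","PROURACIL®","FLUOROURACIL","Fluorouracil",82,High
79,"QUETIAPINE","BIOQUETIN®","BIOQUIN","Hydroquinone",69,High
80,"RALOXIFENE","RALOFEN®","TALOFEN","promazine hydrochloride",78,High
81,"RANITIDINE","ARY-TAC®","ARATAC","amiodarone hydrochloride",78,High
82,"RILUZOLE","RILONORM®","MILONORM","milonorm",80,High
83,"RIVASTIGMINE","CHOLINUP®","CHOLINE","B vitamins",70,High
84,"SOLIFENACIN","SOLIFEX®","SYLIFEX","Silymarin-phospholipides",89,High
85,"SUCCINYLCHOLINE CHLORIDE","MIOKOLIN®","MONOLIN","isosorbide mononitrate",77,High
86,"TADALAFIL","TIAGRIX®","TIARIX","Paroxetine",80,High
87,"TAMSULOSIN","MODALUSIN®","MODAFINIL","Modafinil",57,Medium
88,"TESTOSTRONE ENANTATE","ANDRONE®","ANDROLONE","Nandrolone",84,High
89,"THEOPHYLLINE","THEOMEX®","THEOMAX","ephedrine sulfate/hydroxyzine hydrochloride/theophylline",89,High
90,"TIZANIDINE","SPALEX®","SALEX","Salicylic acid",84,High
91,"TOPIRAMATE","CONVEX®","CONEX","dexbrompheniramine/pseudoephedrine",81,High
92,"TRANEXAMIC ACID","TRANCID®","RANCID","Magnesium Hydroxide",78,High
93,"TRIAMCINOLONE ACETONIDE","CORTIRAN®","CORTIRON","Desoxycortone",90,High
94,"TRIPTORELIN ACETATE","MICRORELIN®","MICROGESTIN","ethinyl estradiol/norethindrone",79,High
95,"VENLAFAXINE","DEPRILAX®","PERILAX","Eperisone",75,High
96,"VITAMIN A","A-VIGEL®","DIVIGEL","estradiol gel/Hormone",75,High
97,"VITAMIN B1/B6/B12","NOROBIT®","NORBIT","Norfloxacin",80,High
98,"VITAMIN B12","VIBALMIN®","VISALMIN","chloramphenicol",90,High
99,"ZOLPIDEM","RAPIDEM®","RAPIDE","diclofenac potassium",78,High
100,"ZONISAMIDE","ZONITED®","ZONITE","Thymol/Propylene Glycol/Benzalkonium/Edetic Acid/Sodium Acetate/Menthol",78,High
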