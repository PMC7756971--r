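entry_id,name,molecular_formula,species,genus,family,compound_class,adduct
1,Ligustilide,C12H14O2,Angelica sinensis,Angelica,Apiaceae,Isobenzofuran,[M+H]+
2,"1,3-Dicaffeoyl-epi-quinic acid",C25H24O12,Chrysanthemum indicum,Chrysanthemum,Asteraceae,Caffeoylquinic acid,[M-H]-
3,Cosmosiin,C21H20O10,Chrysanthemum indicum,Chrysanthemum,Asteraceae,Trihydroxyflavone O-glucosides,[M+H]+
4,6''-Malonylcosmosiin,C24H22O13,Chrysanthemum indicum,Chrysanthemum,Asteraceae,Trihydroxyflavone O-glucosides,[M-H]-
5,Uralsaponin A,C42H62O16,Glycyrrhiza uralensis,Glycyrrhiza,Fabaceae,Oleanane triterpenoid,[M+H]+
6,Liquiritin apioside,C26H30O13,Glycyrrhiza uralensis,Glycyrrhiza,Fabaceae,Flavanone,[M-H]-
7,Isovitexin,C21H20O10,Isatis tinctoria,Isatis,Brassicaceae,Flavone C-glucoside,[M+H]+
8,10-O-p-cis-Coumaroyl scandoside methyl ester,C26H30O13,Oldenlandia diffusa,Oldenlandia,Rubiaceae,Scandoside,[M-H]-
9,E-piceid,C20H22O8,Polygonum cuspidatum,Polygonum,Polygonaceae,Stilbene,[M+H]+
10,Emodin-8-O-glucoside,C21H20O10,Polygonum cuspidatum,Polygonum,Polygonaceae,Anthraquinone,[M-H]-
11,Rosmarinic acid,C18H16O8,Prunella vulgaris,Prunella,Lamiaceae,Rosmarinic lignan,[M+H]+
12,Baicalin,C21H18O11,Scutellaria baicalensis,Scutellaria,Lamiaceae,Flavone O-glucuronides,[M-H]-
13,Wogonoside,C22H20O11,Scutellaria baicalensis,Scutellaria,Lamiaceae,Flavone O-glucuronides,[M+H]+
14,Oroxyloside,C22H20O11,Scutellaria baicalensis,Scutellaria,Lamiaceae,Flavone O-glucuronides,[M-H]-
15,Astilbin,C21H22O11,Smilax glabra,Smilax,Smilacaceae,Flavanone,[M+H]+
16,Oxymatrine,C15H24N2O2,Sophora flavescens,Sophora,Fabaceae,Quinolizidine alkaloid,[M-H]-
17,"Ligustilide (methyl analogue, synthetic)",C13H16O2,Angelica sinensis,Angelica,Apiaceae,Isobenzofuran,[M+H]+
18,"1,3-Dicaffeoyl-epi-quinic acid (methyl analogue, synthetic)",C26H26O12,Chrysanthemum indicum,Chrysanthemum,Asteraceae,Caffeoylquinic acid,[M-H]-
19,"Cosmosiin (methyl analogue, synthetic)",C22H22O10,Chrysanthemum indicum,Chrysanthemum,Asteraceae,Trihydroxyflavone O-glucosides,[M+H]+
20,"6''-Malonylcosmosiin (methyl analogue, synthetic)",C25H24O13,Chrysanthemum indicum,Chrysanthemum,Asteraceae,Trihydroxyflavone O-glucosides,[M-H]-
21,"Uralsaponin A (methyl analogue, synthetic)",C43H64O16,Glycyrrhiza uralensis,Glycyrrhiza,Fabaceae,Oleanane triterpenoid,[M+H]+
22,"Liquiritin apioside (methyl analogue, synthetic)",C27H32O13,Glycyrrhiza uralensis,Glycyrrhiza,Fabaceae,Flavanone,[M-H]-
23,"Isovitexin (methyl analogue, synthetic)",C22H22O10,Isatis tinctoria,Isatis,Brassicaceae,Flavone C-glucoside,[M+H]+
24,"10-O-p-cis-Coumaroyl scandoside methyl ester (methyl analogue, synthetic)",C27H32O13,Oldenlandia diffusa,Oldenlandia,Rubiaceae,Scandoside,[M-H]-
25,"E-piceid (methyl analogue, synthetic)",C21H24O8,Polygonum cuspidatum,Polygonum,Polygonaceae,Stilbene,[M+H]+
26,"Emodin-8-O-glucoside (methyl analogue, synthetic)",C22H22O10,Polygonum cuspidatum,Polygonum,Polygonaceae,Anthraquinone,[M-H]-
27,"Rosmarinic acid (methyl analogue, synthetic)",C19H18O8,Prunella vulgaris,Prunella,Lamiaceae,Rosmarinic lignan,[M+H]+
28,"Baicalin (methyl analogue, synthetic)",C22H20O11,Scutellaria baicalensis,Scutellaria,Lamiaceae,Flavone O-glucuronides,[M-H]-
29,"Wogonoside (methyl analogue, synthetic)",C23H22O11,Scutellaria baicalensis,Scutellaria,Lamiaceae,Flavone O-glucuronides,[M+H]+
30,"Oroxyloside (methyl analogue, synthetic)",C23H22O11,Scutellaria baicalensis,Scutellaria,Lamiaceae,Flavone O-glucuronides,[M-H]-
31,"Astilbin (methyl analogue, synthetic)",C22H24O11,Smilax glabra,Smilax,Smilacaceae,Flavanone,[M+H]+
32,"Oxymatrine (methyl analogue, synthetic)",C16H26N2O2,Sophora flavescens,Sophora,Fabaceae,Quinolizidine alkaloid,[M-H]-
33,"Ligustilide (hydroxy analogue, synthetic)",C12H14O3,Angelica sinensis,Angelica,Apiaceae,Isobenzofuran,[M+H]+
34,"1,3-Dicaffeoyl-epi-quinic acid (hydroxy analogue, synthetic)",C25H24O13,Chrysanthemum indicum,Chrysanthemum,Asteraceae,Caffeoylquinic acid,[M-H]-
35,"Cosmosiin (hydroxy analogue, synthetic)",C21H20O11,Chrysanthemum indicum,Chrysanthemum,Asteraceae,Trihydroxyflavone O-glucosides,[M+H]+
36,"6''-Malonylcosmosiin (hydroxy analogue, synthetic)",C24H22O14,Chrysanthemum indicum,Chrysanthemum,Asteraceae,Trihydroxyflavone O-glucosides,[M-H]-
37,"Uralsaponin A (hydroxy analogue, synthetic)",C42H62O17,Glycyrrhiza uralensis,Glycyrrhiza,Fabaceae,Oleanane triterpenoid,[M+H]+
38,"Liquiritin apioside (hydroxy analogue, synthetic)",C26H30O14,Glycyrrhiza uralensis,Glycyrrhiza,Fabaceae,Flavanone,[M-H]-
39,"Isovitexin (hydroxy analogue, synthetic)",C21H20O11,Isatis tinctoria,Isatis,Brassicaceae,Flavone C-glucoside,[M+H]+
40,"10-O-p-cis-Coumaroyl scandoside methyl ester (hydroxy analogue, synthetic)",C26H30O14,Oldenlandia diffusa,Oldenlandia,Rubiaceae,Scandoside,[M-H]-
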