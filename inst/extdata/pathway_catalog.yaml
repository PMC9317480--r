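# Default biosynthetic-pathway catalog: vitamins riboflavin (B2) and
# biotin (B7) plus the ten essential amino acids, with steps and
# alternative-gene sets drawn from the standard enterobacterial
# biosynthesis gene repertoire. Each step lists the alternative genes able
# to perform it; the catalog is fully user-overridable.
pathways:
  - name: riboflavin
    steps:
      - step: ribA
        enzyme: GTP cyclohydrolase II
        genes: [ribA]
      - step: ribD
        enzyme: diaminohydroxyphosphoribosylaminopyrimidine deaminase/reductase
        genes: [ribD]
      - step: phosphatase
        enzyme: 5-amino-6-(5-phospho-D-ribitylamino)uracil phosphatase
        genes: [yigB, ybjI, yigL]
      - step: ribB
        enzyme: 3,4-dihydroxy-2-butanone-4-phosphate synthase
        genes: [ribB]
      - step: ribH
        enzyme: 6,7-dimethyl-8-ribityllumazine synthase
        genes: [ribH]
      - step: ribE
        enzyme: riboflavin synthase
        genes: [ribE]
      - step: ribC
        enzyme: riboflavin kinase / FAD synthetase
        genes: [ribC, ribF]
  - name: biotin
    steps:
      - step: bioC
        enzyme: malonyl-ACP O-methyltransferase
        genes: [bioC]
      - step: bioH
        enzyme: pimeloyl-ACP methyl ester esterase
        genes: [bioH]
      - step: bioF
        enzyme: 8-amino-7-oxononanoate (KAPA) synthase
        genes: [bioF]
      - step: bioA
        enzyme: adenosylmethionine-8-amino-7-oxononanoate transaminase
        genes: [bioA]
      - step: bioD
        enzyme: dethiobiotin synthetase
        genes: [bioD]
      - step: bioB
        enzyme: biotin synthase
        genes: [bioB]
  - name: histidine
    steps:
      - {step: hisG, enzyme: ATP phosphoribosyltransferase, genes: [hisG]}
      - {step: hisI, enzyme: phosphoribosyl-ATP pyrophosphohydrolase, genes: [hisI]}
      - {step: hisE, enzyme: phosphoribosyl-AMP cyclohydrolase, genes: [hisE]}
      - {step: hisA, enzyme: ProFAR isomerase, genes: [hisA]}
      - {step: hisH, enzyme: IGP synthase glutaminase subunit, genes: [hisH]}
      - {step: hisF, enzyme: IGP synthase cyclase subunit, genes: [hisF]}
      - {step: hisB, enzyme: IGP dehydratase / histidinol-phosphatase, genes: [hisB]}
      - {step: hisC, enzyme: histidinol-phosphate aminotransferase, genes: [hisC]}
      - {step: hisD, enzyme: histidinol dehydrogenase, genes: [hisD]}
  - name: tryptophan
    steps:
      - {step: trpE, enzyme: anthranilate synthase component I, genes: [trpE]}
      - {step: trpG, enzyme: anthranilate synthase component II, genes: [trpG, trpD]}
      - {step: trpD, enzyme: anthranilate phosphoribosyltransferase, genes: [trpD]}
      - {step: trpC, enzyme: indole-3-glycerol phosphate synthase, genes: [trpC]}
      - {step: trpA, enzyme: tryptophan synthase alpha, genes: [trpA]}
      - {step: trpB, enzyme: tryptophan synthase beta, genes: [trpB]}
  - name: phenylalanine
    steps:
      - {step: pheA, enzyme: chorismate mutase / prephenate dehydratase, genes: [pheA]}
      - {step: aminotransferase, enzyme: aromatic aminotransferase, genes: [tyrB, aspC]}
  - name: arginine
    steps:
      - {step: argA, enzyme: N-acetylglutamate synthase, genes: [argA]}
      - {step: argB, enzyme: acetylglutamate kinase, genes: [argB]}
      - {step: argC, enzyme: N-acetylglutamylphosphate reductase, genes: [argC]}
      - {step: argD, enzyme: acetylornithine aminotransferase, genes: [argD]}
      - {step: argE, enzyme: acetylornithine deacetylase, genes: [argE]}
      - {step: argFI, enzyme: ornithine carbamoyltransferase, genes: [argF, argI]}
      - {step: argG, enzyme: argininosuccinate synthase, genes: [argG]}
      - {step: argH, enzyme: argininosuccinate lyase, genes: [argH]}
  - name: lysine
    steps:
      - {step: dapA, enzyme: dihydrodipicolinate synthase, genes: [dapA]}
      - {step: dapB, enzyme: dihydrodipicolinate reductase, genes: [dapB]}
      - {step: dapD, enzyme: tetrahydrodipicolinate succinylase, genes: [dapD]}
      - {step: dapC, enzyme: succinyldiaminopimelate aminotransferase, genes: [dapC, argD]}
      - {step: dapE, enzyme: succinyldiaminopimelate desuccinylase, genes: [dapE]}
      - {step: dapF, enzyme: diaminopimelate epimerase, genes: [dapF]}
      - {step: lysA, enzyme: diaminopimelate decarboxylase, genes: [lysA]}
  - name: methionine
    steps:
      - {step: metA, enzyme: homoserine O-succinyltransferase, genes: [metA]}
      - {step: metB, enzyme: cystathionine gamma-synthase, genes: [metB]}
      - {step: metC, enzyme: cystathionine beta-lyase, genes: [metC]}
      - {step: methylation, enzyme: methionine synthase, genes: [metE, metH]}
  - name: threonine
    steps:
      - {step: thrA, enzyme: aspartokinase / homoserine dehydrogenase, genes: [thrA, metL]}
      - {step: thrB, enzyme: homoserine kinase, genes: [thrB]}
      - {step: thrC, enzyme: threonine synthase, genes: [thrC]}
  - name: isoleucine_valine
    steps:
      - {step: ahas, enzyme: acetohydroxyacid synthase, genes: [ilvB, ilvG, ilvI]}
      - {step: ilvC, enzyme: ketol-acid reductoisomerase, genes: [ilvC]}
      - {step: ilvD, enzyme: dihydroxyacid dehydratase, genes: [ilvD]}
      - {step: ilvE, enzyme: branched-chain aminotransferase, genes: [ilvE]}
  - name: leucine
    steps:
      - {step: leuA, enzyme: 2-isopropylmalate synthase, genes: [leuA]}
      - {step: leuC, enzyme: isopropylmalate isomerase large subunit, genes: [leuC]}
      - {step: leuD, enzyme: isopropylmalate isomerase small subunit, genes: [leuD]}
      - {step: leuB, enzyme: 3-isopropylmalate dehydrogenase, genes: [leuB]}
      - {step: ilvE_leu, enzyme: branched-chain aminotransferase, genes: [ilvE, tyrB]}
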