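species,SL_mm,HL_mm,HL_pctSL,PreD_pctSL,TL_pctSL,CD_pctSL,PecFB_pctSL,DFAe_pctSL,BD_pctSL,ED_pctHL,UJW_pctHL,HW_pctHL,SN_pctHL,M_pctHL,totalGR
C.litoralis,326,67.5,20.7,49.9,121.2,8.4,3.7,19.3,26.6,20,22.4,48.7,24.5,19.7,26
C.suspensus,258.5,52.4,20.3,48.4,122.2,7.5,3.2,17.7,23.2,22.3,24.5,49.2,23.7,18.5,35
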