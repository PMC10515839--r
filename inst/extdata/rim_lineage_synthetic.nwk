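((((((((((RIML,riml_d1),riml_d2),riml_d3),riml_d4),riml_d5),riml_d6),riml_d7),(((((((RIMR,rimr_d1),rimr_d2),rimr_d3),rimr_d4),rimr_d5),rimr_d6),rimr_d7),(((((((ASIL,asil_d1),asil_d2),asil_d3),asil_d4),asil_d5),asil_d6),asil_d7),(((((((ASIR,asir_d1),asir_d2),asir_d3),asir_d4),asir_d5),asir_d6),asir_d7),((((((((ADLL,adll_d1),adll_d2),adll_d3),adll_d4),adll_d5),adll_d6),adll_d7),adll_d8),((((((((ADLR,adlr_d1),adlr_d2),adlr_d3),adlr_d4),adlr_d5),adlr_d6),adlr_d7),adlr_d8),(((((((((ASKL,askl_d1),askl_d2),askl_d3),askl_d4),askl_d5),askl_d6),askl_d7),askl_d8),askl_d9),(((((((((ASKR,askr_d1),askr_d2),askr_d3),askr_d4),askr_d5),askr_d6),askr_d7),askr_d8),askr_d9),(((((((ADAL,adal_d1),adal_d2),adal_d3),adal_d4),adal_d5),adal_d6),adal_d7),(((((((ADAR,adar_d1),adar_d2),adar_d3),adar_d4),adar_d5),adar_d6),adar_d7),(((((((PHBL,phbl_d1),phbl_d2),phbl_d3),phbl_d4),phbl_d5),phbl_d6),phbl_d7),(((((((PHBR,phbr_d1),phbr_d2),phbr_d3),phbr_d4),phbr_d5),phbr_d6),phbr_d7),((((((PVQL,pvql_d1),pvql_d2),pvql_d3),pvql_d4),pvql_d5),pvql_d6),((((((PVQR,pvqr_d1),pvqr_d2),pvqr_d3),pvqr_d4),pvqr_d5),pvqr_d6),(((RICL,ricl_d1),ricl_d2),ricl_d3),(((RICR,ricr_d1),ricr_d2),ricr_d3))ABp,ABa)AB,P1)P0;
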