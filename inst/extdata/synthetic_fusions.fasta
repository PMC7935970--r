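>anchor-syn synthetic stand-in: CC-A_S + FP-sized domain + H10
MGEIAALEQESAALEQENAALEQEIAALEQGSGSGSGSVYMVFRDPARTITMVIMCAIDY
ACMLDSYSFPNSTLFLGYKESLHSHQRHKEESNLPRAVDRCPDFGVFTGLAGIGTLEDLK
AERPDGLLVRLGMYPEDPKRGGSMHPTDLKFPIDDLEKFESKKTSYHGTYKRMFKFAPKA
LIPPNAMVATEPSRPGLATMDKGDGIVAGTSSISAFKNPYQVVPPYNAVGNAALLDAPTQ
DFSASHIVVDRELIFKEDQIADHVNVGLGGSHHHHHHHHHH
>switchA-syn synthetic stand-in: MTS + FP-sized domain + H6 + CC-A_S
MSKLWSKISKLFSGSGSVYMVFRDPARTITMVIMCAIDYACMLDSYSFPNSTLFLGYKES
LHSHQRHKEESNLPRAVDRCPDFGVFTGLAGIGTLEDLKAERPDGLLVRLGMYPEDPKRG
GSMHPTDLKFPIDDLEKFESKKTSYHGTYKRMFKFAPKALIPPNAMVATEPSRPGLATMD
KGDGIVAGTSSISAFKNPYQVVPPYNAVGNAALLDAPTQDFSASHIVVDRELIFKEDQIA
DHVNVGLGGSHHHHHHGSGSEIAALEQESAALEQENAALEQEIAALEQ
>switchB-syn synthetic stand-in: MTS + FP-sized domain + H6 + CC-B_RRS
MSKLWSKISKLFSGSGSVYMVFRDPARTITMVIMCAIDYACMLDSYSFPNSTLFLGYKES
LHSHQRHKEESNLPRAVDRCPDFGVFTGLAGIGTLEDLKAERPDGLLVRLGMYPEDPKRG
GSMHPTDLKFPIDDLEKFESKKTSYHGTYKRMFKFAPKALIPPNAMVATEPSRPGLATMD
KGDGIVAGTSSISAFKNPYQVVPPYNAVGNAALLDAPTQDFSASHIVVDRELIFKEDQIA
DHVNVGLGGSHHHHHHGSGSKIAALRRKSAALKQKNAALKQKIAALKQ
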