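>hsa-miR-9-5p
UCUUUGGUUAUCUAGCUGUAUGA
>hsa-miR-23a-3p
AUCACAUUGCCAGGGAUUUCC
>hsa-miR-24-3p
UGGCUCAGUUCAGCAGGAACAG
>hsa-miR-27a-3p
UUCACAGUGGCUAAGUUCCGC
>hsa-miR-34a-5p
UGGCAGUGUCUUAGCUGGUUGU
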