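>hsa-miR-181b-5p public mature sequence (miRBase spelling)
AACAUUCAUUGCUGUCGGUGGGU
>hsa-miR-107 public mature sequence (miRBase spelling)
AGCAGCAUUGUACAGGGCUAUCA
>hsa-miR-20a-5p public mature sequence (miRBase spelling)
UAAAGUGCUUAUAGUGCAGGUAG
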