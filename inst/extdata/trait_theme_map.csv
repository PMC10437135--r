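"trait_id","theme"
"EA008","kinship"
"EA009","kinship"
"EA011","kinship"
"EA012","kinship"
"EA013","kinship"
"EA015","kinship"
"EA023","kinship"
"EA025","kinship"
"EA027","kinship"
"EA043","kinship"
"EA001","economic"
"EA002","economic"
"EA003","economic"
"EA004","economic"
"EA005","economic"
"EA028","economic"
"EA039","economic"
"EA040","economic"
"EA041","economic"
"EA042","economic"
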