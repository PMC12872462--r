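>insulin mature human insulin, A and B chains concatenated
GIVEQCCTSICSLYQLENYCNFVNQHLCGSHLVEALYLVCGERGFFYTPKT
>insulin_glargine glargine variant: A21G, B chain + RR, chains concatenated
GIVEQCCTSICSLYQLENYCGFVNQHLCGSHLVEALYLVCGERGFFYTPKTRR
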