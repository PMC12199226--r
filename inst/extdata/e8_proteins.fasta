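>insulin|chain1 mature human insulin A chain
GIVEQCCTSICSLYQLENYCN
>insulin|chain2 mature human insulin B chain
FVNQHLCGSHLVEALYLVCGERGFFYTPKT
>transferrin|chain1 synthetic surrogate sequence (not the human serotransferrin sequence; stands in for the 679-residue chain in simulations)
MKWVTFISLLFLFSSAYSRGVFRRDAHKSEVAHRFKDLGEENFKALVLIAFAQYLQQSPF
EDHVKLVNEVTEFAKTSVADESAENSDVSLVNQRLPKVDEPQNLIKQNSELFEQLGEYKF
QNALLVRYTKKVPQVSTPTLVEVSRNLGKVGSKSSLDARFTELSEKERQIKKQTALVELV
KHKPKATKEQLKAVMDDFAAFVEKSSKNPEVAKRMKDSTLQLVAASQAALGL
>fgf2|chain1 human basic fibroblast growth factor (155-residue form)
MAAGSITTLPALPEDGGSGAFPPGHFKDPKRLYCKNGGFFLRIHPDGRVDGVREKSDPHI
KLQLQAEERGVVSIKGVCANRYLAMKEDGRLLASKCVTDECFFFERLESNNYNTYRSRKY
TSWYVALKRTGQYKLGSKTGPGQKAILFLPMSAKS
>tgfb1|chain1 mature human transforming growth factor beta 1
ALDTNYCFSSTEKNCCVRQLYIDFRKDLGWKWIHEPKGYHANFCLGPCPYIWSLDTQYSK
VLALYNQHNPGASAAPCCVPQALEPLPIVYYVGRKPKVEQLSNMIVRSCKCS
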