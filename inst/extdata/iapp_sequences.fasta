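>hIAPP human islet amyloid polypeptide (amylin), 37 aa
KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY
>rIAPP rat amylin (six substitutions in 18-29)
KCNTATCATQRLANFLVRSSNNLGPVLPPTNVGSNTY
>N_terminal_1_20 hIAPP 1-20 fragment
KCNTATCATQRLANFLVHSS
>C_native hIAPP 23-37 C-terminal fragment
FGAILSSTNVGSNTY
>F23R_fragment hIAPP 23-37 fragment, F23R variant
RGAILSSTNVGSNTY
>abeta_core amyloid-beta 25-35 aggregative core
GSNKGAIIGLM
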