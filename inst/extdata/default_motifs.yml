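# Default RBP motif consensi (IUPAC RNA); edit freely and pass via
# read_motif_config() or the CLI --motifs flag.
CPE: UUUUUAU, UUUUAAU
PUM: UGUAHAUA
NRE: AUUGUA
CPSF: AAUAAA
ARE_permissive: AUUUA
ARE_stringent: UUAUUUAUU
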