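"Single-Year Ages Code"	"Year"	"Deaths"	"Population"
"60"	"1999"	"280"	"200000"
"61"	"1999"	"267"	"200000"
"62"	"1999"	"297"	"200000"
"60"	"2000"	"265"	"200000"
"61"	"2000"	"323"	"200000"
"62"	"2000"	"326"	"200000"
"60"	"2001"	"278"	"200000"
"61"	"2001"	"276"	"200000"
"62"	"2001"	"317"	"200000"
"Notes"
"Synthetic example in the CDC WONDER export dialect; not real data."
"Generated by the apcmort synthetic module (seed 11)."
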