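name	iupac	family	provenance
RRACH	RRACH	rrach	consensus
DRACH	DRACH	rrach	consensus_variant
RACH	RACH	rrach	consensus_variant
DRAY	DRAY	rrach	consensus_variant
URACH	URACH	rrach	consensus_variant
DRACG	DRACG	rrach	consensus_variant
GRACH	GRACH	rrach	consensus_variant
ARACH	ARACH	rrach	consensus_variant
DRACU	DRACU	rrach	consensus_variant
RRACU	RRACU	rrach	consensus_variant
GGACH	GGACH	rrach	consensus_variant
AGACH	AGACH	rrach	consensus_variant
GGAU	GGAU	ggau	literature
UGGAU	UGGAU	ggau	extended
AGGAU	AGGAU	ggau	extended
GGAUU	GGAUU	ggau	extended
UGAAC	UGAAC	extended	extended
DRACUCU	DRACUCU	extended	manual
ACUCU	ACUCU	extended	manual
UGGAC	UGGAC	extended	extended
URUAY	URUAY	uruay	literature
URUAU	URUAU	uruay	variant
URUAC	URUAC	uruay	variant
UGUAY	UGUAY	uruay	variant
UUUUU	UUUUU	u_rich	manual
UNUNU	UNUNU	u_rich	manual
URURU	URURU	u_rich	manual
UYUYU	UYUYU	u_rich	manual
YUYUY	YUYUY	u_rich	manual
UUWUU	UUWUU	u_rich	manual
WUUUU	WUUUU	u_rich	manual
UUUUW	UUUUW	u_rich	manual
UUGUU	UUGUU	u_rich	manual
UGUGU	UGUGU	u_rich	manual
YYYYY	YYYYY	y_rich	manual
CUCUC	CUCUC	y_rich	manual
UCUCU	UCUCU	y_rich	manual
YYYYU	YYYYU	y_rich	manual
UYYYY	UYYYY	y_rich	manual
CUCUCU	CUCUCU	y_rich	manual
YUGUM	YUGUM	literature	literature
UGUAMM	UGUAMM	literature	literature
UGWAMH	UGWAMH	literature	literature
UGUAWA	UGUAWA	literature	literature
AUUUA	AUUUA	u_rich	manual
UAUAU	UAUAU	u_rich	manual
GUGUG	GUGUG	other	manual
UUAUU	UUAUU	u_rich	manual
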