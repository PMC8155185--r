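FAO_LIKE	synthetic fatty-acid-oxidation-like maturation set	MATSIG01	MATSIG02	MATSIG03	MATSIG04	MATSIG05	MATSIG06	MATSIG07	MATSIG08	MATSIG09	MATSIG10	MATSIG11	MATSIG12	GRDUP01	GRDUP02	GRDUP03	GRDUP04	GRDUP05	GRDUP06	GRDUP07	GRDUP08
ECM_LIKE	synthetic extracellular-matrix set	ECM01	ECM02	ECM03	ECM04	ECM05	ECM06	ECM07	ECM08	ECM09	ECM10	ECM11	ECM12	ECM13	ECM14	ECM15	ECM16	ECM17	ECM18	ECM19	ECM20
ENDODERM_LIKE	synthetic endoderm marker set	ENDO01	ENDO02	ENDO03	ENDO04	ENDO05	ENDO06	ENDO07	ENDO08	ENDO09	ENDO10	ENDO11	ENDO12	ENDO13	ENDO14	ENDO15
STRESS_LIKE	synthetic ER-stress-like set	STRS01	STRS02	STRS03	STRS04	STRS05	STRS06	STRS07	STRS08
RANDOM_HK	synthetic housekeeping control set	HK0010	HK0050	HK0100	HK0150	HK0200	HK0250	HK0300	HK0350	HK0400	HK0450
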