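2026-09-27 00:37:50 ERROR: unknown key(s) in top level: geom 
2026-09-27 00:38:06 ERROR: unknown key(s) in top level: geom 
2026-09-27 00:38:40 ERROR: unknown key(s) in top level: geom 
2026-09-27 00:39:28 ERROR: unknown key(s) in top level: geom 
2026-09-27 01:07:49 ERROR: unknown key(s) in top level: geom 
2026-09-27 01:23:19 ERROR: unknown key(s) in top level: geom 
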