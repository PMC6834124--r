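outer_pair	inner_pair	dg
AU	AU	-0.93
AU	CG	-2.24
AU	GC	-2.08
AU	GU	-0.5
AU	UA	-1.1
AU	UG	-0.7
CG	AU	-2.11
CG	CG	-3.26
CG	GC	-2.36
CG	GU	-1.5
CG	UA	-2.08
CG	UG	-2.1
GC	AU	-2.35
GC	CG	-3.42
GC	GC	-3.26
GC	GU	-1.5
GC	UA	-2.24
GC	UG	-1.9
GU	AU	-0.7
GU	CG	-1.9
GU	GC	-2.1
GU	GU	-0.5
GU	UA	-0.7
GU	UG	0.5
UA	AU	-1.33
UA	CG	-2.35
UA	GC	-2.11
UA	GU	-0.5
UA	UA	-0.93
UA	UG	-0.7
UG	AU	-0.5
UG	CG	-1.5
UG	GC	-1.5
UG	GU	-0.6
UG	UA	-0.5
UG	UG	-0.5
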