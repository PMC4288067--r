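child	parent
T101	T201
T102	T201
T103	T202
T104	T202
T105	T203
T106	T203
T201	T301
T202	T301
T203	T301
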