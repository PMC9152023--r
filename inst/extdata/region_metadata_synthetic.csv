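"acronym","name","division"
"PL","prelimbic area","isocortex"
"ILA","infralimbic area","olfactory areas"
"LA","lateral amygdala","hippocampal formation"
"BLA","basolateral amygdala","cortical subplate"
"CEA","central amygdala","striatum"
"CA1","hippocampal CA1","pallidum"
"PVT","paraventricular thalamus","thalamus"
"GP","globus pallidus","hypothalamus"
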