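# KOG functional categories: four largest named, remainder aggregated
category	n
general function prediction only	202
signal transduction mechanisms	180
post-translational modification, protein turnover, chaperones	139
cytoskeleton	85
remaining categories (aggregated)	463
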