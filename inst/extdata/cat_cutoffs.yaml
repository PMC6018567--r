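# CAT impairment cut-offs: highest T-score counted as impaired (inclusive)
spk_pn: 61      # spoken picture naming
writt_pn: 54    # written picture naming
rep_n: 52       # nonword repetition
sem_m: 50       # semantic associations
cspk_w: 52      # spoken word comprehension
writt_copy: 51  # writing copy
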