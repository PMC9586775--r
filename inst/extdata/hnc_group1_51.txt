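# Survival times (days) of 51 head-and-neck cancer patients treated with
# radiotherapy (Lawless). A trailing * marks a right-censored time.
7 34 42 63 64 74* 83 84 91 108 112 129 133 133 139 140 140 146 149 154
157 160 160 165 173 176 185* 218 225 241 248 273 277 279* 297 319* 405
417 420 440 523 523* 583 594 1101 1116* 1146 1226* 1349* 1412* 1417
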