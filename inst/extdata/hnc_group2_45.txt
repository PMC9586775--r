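# Survival times (days) of 45 head-and-neck cancer patients treated with
# radiotherapy plus chemotherapy (Lawless). A trailing * marks a
# right-censored time.
37 84 92 94 110 112 119 127 130 133 140 146 155 159 169* 173 179 194
195 209 249 281 319 339 432 469 519 528* 547* 613* 633 725 759* 817
1092* 1245* 1331* 1557* 1642* 1771* 1776 1897* 2023* 2146* 2297*
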