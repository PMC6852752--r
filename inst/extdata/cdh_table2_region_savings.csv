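region,realized,unrealized
BC,7174406,104539164
AB,3332450,138074937
SK,1174422,27029365
MB,2232171,41071172
ON,21988985,349443270
QC,8019828,269342139
NB,912786,39986984
NS,615111,49676400
PEI/NL,709443,28220107
TOTAL,46168848,1048711394
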