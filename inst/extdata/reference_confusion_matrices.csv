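dataset,learning_rate,true,ST,SI,WA
own100_OR,0.0002,ST,441,240,0
own100_OR,0.0002,SI,113,560,0
own100_OR,0.0002,WA,0,1,700
own100_OR,0.006,ST,0,681,0
own100_OR,0.006,SI,0,673,0
own100_OR,0.006,WA,0,2,699
own100_OR,0.003,ST,409,272,0
own100_OR,0.003,SI,98,575,0
own100_OR,0.003,WA,0,1,700
own100_OR,0.015,ST,0,0,681
own100_OR,0.015,SI,0,0,673
own100_OR,0.015,WA,0,0,701
own100_OR,0.01,ST,0,0,681
own100_OR,0.01,SI,0,0,673
own100_OR,0.01,WA,0,0,701
own200_OR,0.0002,ST,547,153,0
own200_OR,0.0002,SI,154,1066,0
own200_OR,0.0002,WA,0,0,694
own200_OR,0.006,ST,550,149,1
own200_OR,0.006,SI,168,1052,0
own200_OR,0.006,WA,1,0,693
own200_OR,0.003,ST,555,145,0
own200_OR,0.003,SI,150,1070,0
own200_OR,0.003,WA,0,0,694
own200_OR,0.015,ST,81,580,39
own200_OR,0.015,SI,33,1177,10
own200_OR,0.015,WA,0,0,694
own200_OR,0.01,ST,13,656,31
own200_OR,0.01,SI,3,1207,10
own200_OR,0.01,WA,1,0,693
own100_OR+LA1,0.0002,ST,437,244,0
own100_OR+LA1,0.0002,SI,106,567,0
own100_OR+LA1,0.0002,WA,0,1,700
own100_OR+LA1,0.006,ST,97,584,0
own100_OR+LA1,0.006,SI,18,655,0
own100_OR+LA1,0.006,WA,1,0,700
own100_OR+LA1,0.003,ST,416,265,0
own100_OR+LA1,0.003,SI,103,570,0
own100_OR+LA1,0.003,WA,0,1,700
own100_OR+LA1,0.015,ST,0,681,0
own100_OR+LA1,0.015,SI,0,673,0
own100_OR+LA1,0.015,WA,0,1,700
own100_OR+LA1,0.01,ST,0,680,1
own100_OR+LA1,0.01,SI,0,673,0
own100_OR+LA1,0.01,WA,0,0,701
own100_OR+LA1+SH+LA2,0.0002,ST,406,273,2
own100_OR+LA1+SH+LA2,0.0002,SI,91,578,4
own100_OR+LA1+SH+LA2,0.0002,WA,7,2,692
own100_OR+LA1+SH+LA2,0.006,ST,0,681,0
own100_OR+LA1+SH+LA2,0.006,SI,0,678,0
own100_OR+LA1+SH+LA2,0.006,WA,0,701,0
own100_OR+LA1+SH+LA2,0.003,ST,391,289,1
own100_OR+LA1+SH+LA2,0.003,SI,102,571,0
own100_OR+LA1+SH+LA2,0.003,WA,10,0,691
own100_OR+LA1+SH+LA2,0.015,ST,0,0,681
own100_OR+LA1+SH+LA2,0.015,SI,0,0,673
own100_OR+LA1+SH+LA2,0.015,WA,0,0,701
own100_OR+LA1+SH+LA2,0.01,ST,0,681,0
own100_OR+LA1+SH+LA2,0.01,SI,0,673,0
own100_OR+LA1+SH+LA2,0.01,WA,0,8,693
own200_OR+LA1,0.0002,ST,578,121,1
own200_OR+LA1,0.0002,SI,219,1001,0
own200_OR+LA1,0.0002,WA,0,0,694
own200_OR+LA1,0.006,ST,223,477,0
own200_OR+LA1,0.006,SI,88,1132,0
own200_OR+LA1,0.006,WA,0,0,694
own200_OR+LA1,0.003,ST,537,168,0
own200_OR+LA1,0.003,SI,140,1080,0
own200_OR+LA1,0.003,WA,0,0,694
own200_OR+LA1,0.015,ST,56,611,33
own200_OR+LA1,0.015,SI,21,1188,11
own200_OR+LA1,0.015,WA,1,0,693
own200_OR+LA1,0.01,ST,56,611,33
own200_OR+LA1,0.01,SI,21,1188,11
own200_OR+LA1,0.01,WA,1,0,693
uci_OR+LA1,0.0002,ST,455,67,10
uci_OR+LA1,0.0002,SI,153,337,1
uci_OR+LA1,0.0002,WA,0,0,496
uci_OR+LA1,0.006,ST,525,0,7
uci_OR+LA1,0.006,SI,485,1,5
uci_OR+LA1,0.006,WA,0,0,496
uci_OR+LA1,0.003,ST,471,57,4
uci_OR+LA1,0.003,SI,107,383,1
uci_OR+LA1,0.003,WA,0,0,496
uci_OR+LA1,0.015,ST,532,0,0
uci_OR+LA1,0.015,SI,491,0,0
uci_OR+LA1,0.015,WA,496,0,0
uci_OR+LA1,0.01,ST,532,0,0
uci_OR+LA1,0.01,SI,491,0,0
uci_OR+LA1,0.01,WA,496,0,0
uci_OR,0.0002,ST,480,48,4
uci_OR,0.0002,SI,145,344,2
uci_OR,0.0002,WA,3,0,493
uci_OR,0.006,ST,532,0,0
uci_OR,0.006,SI,491,0,0
uci_OR,0.006,WA,496,0,0
uci_OR,0.003,ST,319,210,3
uci_OR,0.003,SI,325,160,6
uci_OR,0.003,WA,0,4,492
uci_OR,0.015,ST,0,528,4
uci_OR,0.015,SI,0,486,5
uci_OR,0.015,WA,0,0,496
uci_OR,0.01,ST,0,530,2
uci_OR,0.01,SI,0,486,5
uci_OR,0.01,WA,0,2,494
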