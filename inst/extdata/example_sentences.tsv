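ex1	en	even though most of his inventions were not actually built in his lifetime, many of today’s modern machines can be traced back to some of his original designs
ex2	en	the wedding was ruined by the heavy rain and snow
ex3	en	the royal couple married in a beautiful wedding ceremony
ex4	en	The athlete ran as she crossed the finish line of the marathon
ex5	en	The bride ran as she saw the groom in the wedding
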