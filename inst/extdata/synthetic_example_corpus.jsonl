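{"id":"ex01","text":"smoking a blunt with friends tonight feeling blessed","urls":[],"lang":"en","source":"personal","sentiment":"positive"}
{"id":"ex02","text":"I drink lean and smoke dabs every day get faded","urls":[],"lang":"en","source":"personal","sentiment":"positive"}
{"id":"ex03","text":"don't love how they penalized him for smoking weed","urls":[],"lang":"en","source":"personal","sentiment":"negative"}
{"id":"ex04","text":"BREAKING lawmakers vote on cannabis legalization https://t.co/m0001","urls":["https://t.co/m0001"],"lang":"en","source":"media","sentiment":"neutral"}
{"id":"ex05","text":"new study on marijuana edibles policy https://t.co/m0002","urls":["https://t.co/m0002"],"lang":"en","source":"media","sentiment":"neutral"}
{"id":"ex06","text":"weekend sale on vape cartridges order now https://t.co/r0001","urls":["https://t.co/r0001"],"lang":"en","source":"retail","sentiment":"neutral"}
{"id":"ex07","text":"k2 spice in stock free shipping https://t.co/r0002","urls":["https://t.co/r0002"],"lang":"en","source":"retail","sentiment":"neutral"}
{"id":"ex08","text":"that comment was blunt","urls":[],"lang":"en","source":"personal","sentiment":"neutral"}
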