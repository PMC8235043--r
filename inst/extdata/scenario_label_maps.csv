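scenario,method,aoi,label
01-car pursuit,IC,red car,streetcar
01-car pursuit,IC,red car,sports car
01-car pursuit,IC,red car,minivan
01-car pursuit,IC,red car,cab
01-car pursuit,IC,red car,minibus
01-car pursuit,IC,red car,limousine
01-car pursuit,IC,red car,car mirror
01-car pursuit,IC,red car,racer
01-car pursuit,IC,red car,passenger car
01-car pursuit,IC,white car,
01-car pursuit,OD,red car,car
01-car pursuit,OD,white car,
02-turning car,IC,red car,streetcar
02-turning car,IC,red car,sports car
02-turning car,IC,red car,minivan
02-turning car,IC,red car,cab
02-turning car,IC,red car,minibus
02-turning car,IC,red car,limousine
02-turning car,IC,red car,car mirror
02-turning car,IC,red car,racer
02-turning car,IC,red car,passenger car
02-turning car,OD,red car,car
03-dialog,IC,left face,ear
03-dialog,IC,right face,
03-dialog,IC,shirt,sweatshirt
03-dialog,OD,left face,person
03-dialog,OD,right face,
03-dialog,OD,shirt,
04-thimblerig,IC,cup1,cocktail shaker
04-thimblerig,IC,cup1,coffee mug
04-thimblerig,IC,cup1,cup
04-thimblerig,IC,cup2,
04-thimblerig,IC,cup3,
04-thimblerig,OD,cup1,cup
04-thimblerig,OD,cup2,bowl
04-thimblerig,OD,cup3,
05-memory,IC,cards,desk
05-memory,OD,cards,dining table
06-UNO,IC,left hand,
06-UNO,IC,right hand,
06-UNO,IC,stack covered,desk
06-UNO,IC,stack uncovered,
06-UNO,OD,left hand,person
06-UNO,OD,right hand,
06-UNO,OD,stack covered,dining table
06-UNO,OD,stack uncovered,
07-kite,IC,person,lab coat
07-kite,IC,person,poncho
07-kite,IC,person,cardigan
07-kite,IC,person,cloak
07-kite,IC,person,sweatshirt
07-kite,IC,person,trench coat
07-kite,IC,kite,balloon
07-kite,IC,kite,kite
07-kite,IC,kite,parachute
07-kite,OD,person,person
07-kite,OD,kite,kite
08-case exchange,IC,persons,sombrero
08-case exchange,IC,persons,cowboy hat
08-case exchange,IC,textbox,
08-case exchange,IC,case,mailbag
08-case exchange,IC,case,packet
08-case exchange,IC,case,plastic bag
08-case exchange,IC,case,shopping basket
08-case exchange,IC,case,backpack
08-case exchange,IC,case,bucket
08-case exchange,IC,case,crate
08-case exchange,IC,suspects,lab coat
08-case exchange,IC,suspects,poncho
08-case exchange,IC,suspects,cardigan
08-case exchange,IC,suspects,cloak
08-case exchange,IC,suspects,sweatshirt
08-case exchange,IC,suspects,trench coat
08-case exchange,OD,persons,person
08-case exchange,OD,textbox,
08-case exchange,OD,case,handbag
08-case exchange,OD,case,suitcase
08-case exchange,OD,suspects,
09-ball game,IC,ball,baseball
09-ball game,IC,ball,basketball
09-ball game,IC,ball,rugby ball
09-ball game,IC,ball,tennis ball
09-ball game,IC,ball,volleyball
09-ball game,IC,ball,soccer ball
09-ball game,IC,player white,ballplayer
09-ball game,IC,player red1,
09-ball game,IC,player red2,
09-ball game,IC,player red3,
09-ball game,OD,ball,sports ball
09-ball game,OD,player white,person
09-ball game,OD,player red1,
09-ball game,OD,player red2,
09-ball game,OD,player red3,
10-bag search,IC,red bag,plastic bag
10-bag search,IC,yellow bag,
10-bag search,IC,blue bag,
10-bag search,IC,red-white bag,
10-bag search,IC,brown bag,mailbag
10-bag search,IC,persons,lab coat
10-bag search,IC,persons,poncho
10-bag search,IC,persons,cardigan
10-bag search,IC,persons,cloak
10-bag search,IC,persons,sweatshirt
10-bag search,IC,persons,trench coat
10-bag search,OD,red bag,handbag
10-bag search,OD,yellow bag,
10-bag search,OD,blue bag,
10-bag search,OD,red-white bag,
10-bag search,OD,brown bag,
10-bag search,OD,persons,person
11-person search,IC,hooded,lab coat
11-person search,IC,hooded,poncho
11-person search,IC,hooded,cardigan
11-person search,IC,hooded,cloak
11-person search,IC,hooded,sweatshirt
11-person search,IC,hooded,trench coat
11-person search,IC,red shirt and hat,sombrero
11-person search,IC,red shirt and hat,cowboy hat
11-person search,IC,persons,
11-person search,OD,hooded,person
11-person search,OD,red shirt and hat,
11-person search,OD,persons,
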